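# Minimal three-horse scenario: one aisle, two pastures, one worker.
horses:
  - {id: horse_1, stall: 1, aisle: A, weekday_pasture: pasture_1}
  - {id: horse_2, stall: 2, aisle: A, weekday_pasture: pasture_1}
  - {id: horse_3, stall: 3, aisle: A, weekday_pasture: pasture_2}
people:
  - {id: worker_1, shift_start_s: 25200, shift_end_s: 57600}
static_tags:
  - {id: pasture_1, kind: pasture, link: pasture_1}
  - {id: pasture_2, kind: pasture, link: pasture_2}
  - {id: barn_door_1, kind: barn_door}
  - {id: aisle_A, kind: aisle, link: A}
bookkeeping_tag_id: bookkeeping
n_days: 2
day0_weekday: Tuesday
turnout_start_s: 30600
turnout_end_s: 59400
weekend_days: []
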