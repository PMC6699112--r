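# Facility map: rooms a tagged blood product can report, with cooling and
# stop-box flags; ambient temperatures are used only by the simulator.
rooms:
  - location_id: btl
    room_type: BTL
    has_validated_cooler: true
    has_stopbox: false
    ambient_c: 4.0
  - location_id: corridor
    room_type: corridor
    has_validated_cooler: false
    has_stopbox: false
    ambient_c: 22.0
  - location_id: or_storage
    room_type: storage_room
    has_validated_cooler: true
    has_stopbox: true
    ambient_c: 4.0
  - location_id: or_theatre
    room_type: or_theatre
    has_validated_cooler: false
    has_stopbox: true
    ambient_c: 22.0
  - location_id: icu_storage
    room_type: storage_room
    has_validated_cooler: true
    has_stopbox: true
    ambient_c: 4.0
  - location_id: icu_bay
    room_type: icu_bay
    has_validated_cooler: false
    has_stopbox: false
    ambient_c: 22.0
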