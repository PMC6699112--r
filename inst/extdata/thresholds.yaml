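# Guideline thresholds (defaults written out explicitly).
storage_lo_c: 2.0
storage_hi_c: 6.0
tolerance_c: 0.5
breach_c: 10.0
breach_noncompliant_c: 11.0
transfusion_max_hours: 1.0
breach_transfuse_within_hours: 24.0
return_within_hours: 24.0
min_allocation_hours: 1.0
gap_limit_min: 24.0
max_plausible_transfusion_hours: 24.0
g3_anchor: breach
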