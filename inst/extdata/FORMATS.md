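# File formats

All formats are UTF-8 CSV with '.' decimal separators. Metadata travels as
`#`-prefixed `key=value` lines above an ordinary column-titled CSV body.

## Track CSV (`example_track.csv`)

Header keys (all required): `arena_diameter_cm`, `rotation_speed_deg_per_s`
(signed, positive = counter-clockwise), `sector_center_deg`,
`sector_width_deg`, `session_duration_s`, `phase_label` (one of
`habituation`, `acquisition`, `retrieval`, `reversal`), `rat_id`,
`group_label`, `session_index`. Writers add `n_rows` so empty sessions are
explicit.

Body columns: `t_s` (strictly increasing seconds since session start),
`x_cm`, `y_cm` (room frame, origin at arena center, x right / y up,
counter-clockwise angles), `shock_flag` (1 at shock onsets, else 0).

Validation: radius must not exceed arena radius + 0.5 cm (tracking
jitter tolerance); violations are rejected with the row named.

## Activity CSV (`example_activity.csv`)

Header keys: `start_timestamp`, `bin_width_min`, `schedule` as
semicolon-separated `start-end:state` intervals in minutes
(`state` in {light, dark}) which must tile the recording exactly.
Body: one `count` column of non-negative integer activity counts per bin.

## Annotation CSV

Flat CSV, one row per rat: `rat_id`, `group_label`, `litter_id`,
`shock_intensity_mA`, per-session `defecation_*`, per-session
`saccharin_g_s<k>` / `water_g_s<k>` masses (grams, non-negative), and
per-trial `latency_s_t<k>` step-through latencies (seconds, capped at
300).
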