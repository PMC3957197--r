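# arena_diameter_cm=82
# rotation_speed_deg_per_s=6
# sector_center_deg=0
# sector_width_deg=60
# session_duration_s=3
# phase_label=acquisition
# rat_id=demo1
# group_label=control
# session_index=1
# n_rows=4
t_s,x_cm,y_cm,shock_flag
0,25,0,1
1,24.5,4.2,0
2,23.1,8.6,0
3,21.4,12.4,0
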