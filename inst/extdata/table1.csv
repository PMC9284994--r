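swine,lesion_site,acuity,probe_pattern_deg,probe_length_mm,acoustic_power_W,duration_s,max_temp_rise_C,time_to_baseline_s,histology_volume_cm3,mrti_volume_cm3,included,exclusion_reason,note
1,Center,Acute,360,7,3,100,NA,NA,NA,NA,FALSE,no recorded measurements,probe did not reach target
1,Right,Acute,360,7,3,100,13.00,135,2.49,0.15,FALSE,suboptimal staining,
2,Center,Acute,360,7,3,100,22.00,100,0.25,0.30,TRUE,,
2,Right,Acute,360,7,4,100,23.07,100,0.60,0.35,TRUE,,
3,Center,Acute,360,7,4,120,7,150,3.693,0.4,FALSE,suboptimal staining,
4,Right,Acute,360,7,6,180,16,180,0.92,0.9,TRUE,,probe ablated about 320 of 360 degrees and was replaced afterwards
5,Center,Subacute,360,7,3,120,8,120,0.44,0.4,TRUE,,
6,Right,Subacute,360,7,3,120,9.6,120,0.48,0.45,TRUE,,robot stalled and the probe was manually inserted
7,Right,Subacute,180,7,3,120,10,90,0.27,0.25,TRUE,,
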