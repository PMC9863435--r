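product_id,run_label,arc,auc,arc_sd,auc_sd
Reference,run1,37.80,77.46,2.01,13.48
T1,run1,32.89,77.62,1.60,13.75
Reference,run2,38.47,77.46,1.35,13.48
T2,run2,27.42,60.98,0.99,10.30
T3,run2,51.20,96.78,0.60,15.77
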