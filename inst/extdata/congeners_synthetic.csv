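peak_id,n_cl,log_kow,k_h,k_d,mw
PCB4,2,4.65,0.012,2500,223.1
PCB19,3,5.02,0.015,5000,257.54
PCB118,5,6.74,0.006,50000,326.43
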