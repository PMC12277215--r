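{"theta":{"T_stride":1.1,"stride_length":1.32,"hip":[0.1031,0.342,-0.0418,-0.0548,-0.0202],"knee":[0.4719,-0.092,-0.3395,-0.2189,0.1833],"ankle":[0.02,0.08,-0.05],"pelvis_fluct":[0.012,0],"stance_load_threshold":0.2},"anthro":{"total_mass":75,"height":1.75},"scenario":{"slope_deg":-5,"target_speed":1.2,"duration":10,"dt":0.01,"gravity":9.81,"speed_tolerance":0.15}}
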