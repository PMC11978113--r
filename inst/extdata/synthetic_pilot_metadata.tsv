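sample_id	group
ctrl_001	control
ctrl_002	control
ctrl_003	control
ctrl_004	control
ctrl_005	control
ctrl_006	control
ctrl_007	control
ctrl_008	control
ctrl_009	control
ctrl_010	control
trt_001	treatment
trt_002	treatment
trt_003	treatment
trt_004	treatment
trt_005	treatment
trt_006	treatment
trt_007	treatment
trt_008	treatment
trt_009	treatment
trt_010	treatment
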