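label	kd	kd_err
free	2.1e-9	1.0e-9
EB-47	1.3e-10	0.7e-10
veliparib	4.2e-9	1.1e-9
olaparib	2.1e-9	0.4e-9
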