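target,model,n_wavelengths,lvs,r_c,rmsec,r_cv,rmsecv,r_p,rmsep
leaf,F-PLSR,460,17,0.974,0.156,0.924,0.269,0.934,0.223
leaf,RF-PLSR,10,3,0.817,0.401,0.798,0.420,0.828,0.356
stem,F-PLSR,460,16,0.987,0.063,0.917,0.168,0.930,0.084
stem,RF-PLSR,9,5,0.820,0.229,0.773,0.254,0.724,0.157
root,F-PLSR,460,11,0.992,0.020,0.931,0.064,0.915,0.045
root,RF-PLSR,7,7,0.773,0.097,0.592,0.130,0.797,0.068
whole_plant,F-PLSR,460,6,0.904,0.388,0.893,0.409,0.908,0.351
whole_plant,RF-PLSR,8,4,0.878,0.451,0.874,0.468,0.876,0.426
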