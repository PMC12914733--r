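compartment,total_T_cells,cd4_cd8_ratio,predicted_max_cd4,source
blood,8e9,2.0,5.09e9,whole-body T-cell census / homeostatic model maximum
lymphoid,3.6e11,2.0,2.02e11,whole-body T-cell census / homeostatic model maximum
git,1.7e10,1.0,8.25e9,whole-body T-cell census / homeostatic model maximum
lung,1.3e10,1.0,4.14e9,whole-body T-cell census / homeostatic model maximum
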