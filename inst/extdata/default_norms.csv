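test,source,intercept,age_slope,edu_slope,sd,direction
digit_span_forward,published_norm,9.0,-0.03,0.08,2.0,higher_is_better
digit_span_backward,published_norm,7.5,-0.03,0.08,2.0,higher_is_better
mwcst_errors,published_norm,1.0,0.08,-0.15,3.0,higher_is_worse
fluency_alternating,published_norm,20.0,-0.12,0.30,4.0,higher_is_better
fluency_semantic,published_norm,30.0,-0.15,0.35,5.0,higher_is_better
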