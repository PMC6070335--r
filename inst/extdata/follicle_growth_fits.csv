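follicle_id,y0,k,tau,doubling_time,r_squared
Fo1,2.5e-6,0.110,9.06,6.28,0.9980
Fo2,0.022,0.053,18.73,12.98,0.9890
Fo3,1.469,0.018,56.49,39.15,0.5811
Fo4,0.001,0.072,13.82,9.58,0.9998
Fo5,0.120,0.046,21.66,15.01,0.9781
Fo6,0.005,0.055,18.13,12.57,0.9895
Fo7,0.010,0.055,18.26,12.66,0.9820
Fo8,0.472,0.014,69.67,48.29,0.5779
Average,0.011,0.056,17.86,12.38,0.9996
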