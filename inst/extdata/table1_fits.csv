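panel,color,t0,h,h_ps,Q,t0_err,h_err,h_ps_err,Q_err,sigma_printed,r2_printed
a,darkgreen,251.0,5754,5701,299,4.8,16.1,15.9,4.3,0.003,0.997
a,lightgreen,235.2,5086,5049,275,2.2,4.7,4.66,0.8,0.004,0.999
a,yellowgreen,216.4,5761,5727,278,8.6,14.4,14.3,1.47,0.004,0.992
b,darkgreen,247.6,4018,3955,279,5.62,13.6,13.3,5.2,0.004,0.998
b,lightgreen,289.4,1973,1930,273,2.5,11.3,11.0,10.2,0.004,0.999
c,darkgreen,260.6,2134,2141,233,0.42,1.8,1.9,0.7,0.004,0.994
d,darkgreen,241.2,1954,2068,32,2.4,8.3,7.6,9.4,0.032,0.999
d,forestgreen,238.2,1792,1981,28,1.6,6.7,6.28,8.0,0.035,0.999
d,yellowgreen,245.3,1267,1476,19,1.0,5.7,5.5,6.5,0.052,0.999
d,lightgreen,215.9,1971,2428,29,1.6,8.2,6.7,11.8,0.034,0.997
d,limegreen,215.9,1771,2292,24,2.1,11.8,9.3,16.0,0.042,0.993
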