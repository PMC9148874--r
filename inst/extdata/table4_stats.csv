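method,rmse,pearson,kendall,me
FM(PM6-D3H4),3.61,0.81,0.62,-3.26
FM(GFN-2),5.16,0.48,0.43,-4.52
FM(wB97X-D),3.69,0.62,0.33,-2.92
PM6-D3H4,2.43,0.78,0.52,-0.69
GFN-2,2.94,0.58,0.52,-0.50
wB97X-D,3.86,0.74,0.62,-0.23
wB97X-D(blur),5.98,0.79,0.43,-4.42
BLYP,5.09,0.66,0.52,-0.13
BLYP(blur),5.52,0.75,0.52,-3.02
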