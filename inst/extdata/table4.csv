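method,guest,value,uncertainty
FM(PM6-D3H4),G1,-12.0,0.6
FM(PM6-D3H4),G2,-13.5,1.2
FM(PM6-D3H4),G3,-16.4,1.1
FM(PM6-D3H4),G4,-14.2,0.5
FM(PM6-D3H4),G5,-12.5,0.6
FM(PM6-D3H4),G6,-18.4,1.3
FM(PM6-D3H4),G7,-9.8,1.6
FM(GFN-2),G1,-13.7,0.7
FM(GFN-2),G2,-13.9,0.9
FM(GFN-2),G3,-16.5,0.7
FM(GFN-2),G4,-15.5,0.9
FM(GFN-2),G5,-11.3,0.7
FM(GFN-2),G6,-20.0,0.7
FM(GFN-2),G7,-14.7,0.9
FM(wB97X-D),G1,-12.4,1.0
FM(wB97X-D),G2,-10.4,0.4
FM(wB97X-D),G3,-16.1,0.5
FM(wB97X-D),G4,-15.3,0.7
FM(wB97X-D),G5,-10.9,1.9
FM(wB97X-D),G6,-18.1,2.1
FM(wB97X-D),G7,-11.2,0.8
PM6-D3H4,G1,-9.4,1.1
PM6-D3H4,G2,-11.8,2.5
PM6-D3H4,G3,-12.2,2.1
PM6-D3H4,G4,-11.2,2.2
PM6-D3H4,G5,-9.7,3.5
PM6-D3H4,G6,-18.7,1.7
PM6-D3H4,G7,-5.8,2.7
GFN-2,G1,-7.9,0.8
GFN-2,G2,-7.4,1.0
GFN-2,G3,-9.4,0.9
GFN-2,G4,-11.4,1.1
GFN-2,G5,-18.7,3.6
GFN-2,G6,-12.6,0.8
GFN-2,G7,-10.1,1.5
wB97X-D,G1,-9.1,0.5
wB97X-D,G2,-12.6,1.7
wB97X-D,G3,-15.5,0.8
wB97X-D,G4,-9.7,1.0
wB97X-D,G5,-10.2,1.8
wB97X-D,G6,-18.1,1.0
wB97X-D,G7,-0.4,2.1
wB97X-D(blur),G1,-11.0,0.5
wB97X-D(blur),G2,-15.0,1.8
wB97X-D(blur),G3,-19.0,0.9
wB97X-D(blur),G4,-20.8,0.9
wB97X-D(blur),G5,-14.6,4.0
wB97X-D(blur),G6,-20.6,1.0
wB97X-D(blur),G7,-3.9,2.0
BLYP,G1,-9.9,0.5
BLYP,G2,-11.9,1.6
BLYP,G3,-15.7,0.8
BLYP,G4,-14.5,0.9
BLYP,G5,-8.7,2.6
BLYP,G6,-17.3,1.0
BLYP,G7,3.1,2.2
BLYP(blur),G1,-11.6,0.5
BLYP(blur),G2,-13.0,1.6
BLYP(blur),G3,-17.8,1.0
BLYP(blur),G4,-21.1,1.0
BLYP(blur),G5,-14.5,0.8
BLYP(blur),G6,-19.4,1.0
BLYP(blur),G7,-4.0,2.3
Exp.,G1,-7.05,
Exp.,G2,-9.94,
Exp.,G3,-11.6,
Exp.,G4,-11.2,
Exp.,G5,-12.3,
Exp.,G6,-14.1,
Exp.,G7,-7.79,
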