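element,matrix,mpl
Cu,wine,1
Zn,wine,5
Pb,wine,0.15
Cd,wine,0.01
As,wine,0.2
Cu,must,10
Zn,must,10
Pb,must,0.5
Cd,must,0.01
As,must,0.2
Ni,wine,NA
Co,wine,NA
Cr,wine,NA
Hg,wine,NA
Ni,must,NA
Co,must,NA
Cr,must,NA
Hg,must,NA
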