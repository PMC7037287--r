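pair,variety,element,ratio
root/soil,Feteasca alba,Cu,0.411
root/soil,Feteasca alba,Zn,0.201
root/soil,Feteasca alba,Pb,0.055
root/soil,Feteasca alba,Cd,0.529
root/soil,Feteasca alba,Ni,0.995
root/soil,Feteasca alba,Co,1.302
root/soil,Feteasca alba,As,1.025
root/soil,Feteasca alba,Cr,2.677
root/soil,Feteasca alba,Hg,0.938
root/soil,Feteasca regala,Cu,0.418
root/soil,Feteasca regala,Zn,0.187
root/soil,Feteasca regala,Pb,0.055
root/soil,Feteasca regala,Cd,0.639
root/soil,Feteasca regala,Ni,0.967
root/soil,Feteasca regala,Co,2.895
root/soil,Feteasca regala,As,1.23
root/soil,Feteasca regala,Cr,3.457
root/soil,Feteasca regala,Hg,0.759
root/soil,Riesling italian,Cu,0.534
root/soil,Riesling italian,Zn,0.156
root/soil,Riesling italian,Pb,0.051
root/soil,Riesling italian,Cd,0.566
root/soil,Riesling italian,Ni,0.477
root/soil,Riesling italian,Co,2.317
root/soil,Riesling italian,As,1.637
root/soil,Riesling italian,Cr,2.571
root/soil,Riesling italian,Hg,0.105
cane/soil,Feteasca alba,Cu,0.076
cane/soil,Feteasca alba,Zn,0.174
cane/soil,Feteasca alba,Pb,0.062
cane/soil,Feteasca alba,Cd,0.981
cane/soil,Feteasca alba,Ni,0.782
cane/soil,Feteasca alba,Co,1.023
cane/soil,Feteasca alba,As,0.758
cane/soil,Feteasca alba,Cr,0.725
cane/soil,Feteasca alba,Hg,1.062
cane/soil,Feteasca regala,Cu,0.085
cane/soil,Feteasca regala,Zn,0.185
cane/soil,Feteasca regala,Pb,0.066
cane/soil,Feteasca regala,Cd,1.083
cane/soil,Feteasca regala,Ni,0.922
cane/soil,Feteasca regala,Co,8.631
cane/soil,Feteasca regala,As,0.685
cane/soil,Feteasca regala,Cr,0.564
cane/soil,Feteasca regala,Hg,1.191
cane/soil,Riesling italian,Cu,0.085
cane/soil,Riesling italian,Zn,0.186
cane/soil,Riesling italian,Pb,0.058
cane/soil,Riesling italian,Cd,0.933
cane/soil,Riesling italian,Ni,0.786
cane/soil,Riesling italian,Co,7.114
cane/soil,Riesling italian,As,0.936
cane/soil,Riesling italian,Cr,0.642
cane/soil,Riesling italian,Hg,0.16
leaf/soil,Feteasca alba,Cu,0.08
leaf/soil,Feteasca alba,Zn,0.163
leaf/soil,Feteasca alba,Pb,0.076
leaf/soil,Feteasca alba,Cd,0.625
leaf/soil,Feteasca alba,Ni,2.98
leaf/soil,Feteasca alba,Co,3.897
leaf/soil,Feteasca alba,As,2.071
leaf/soil,Feteasca alba,Cr,0.362
leaf/soil,Feteasca alba,Hg,2.123
leaf/soil,Feteasca regala,Cu,0.081
leaf/soil,Feteasca regala,Zn,0.145
leaf/soil,Feteasca regala,Pb,0.069
leaf/soil,Feteasca regala,Cd,0.802
leaf/soil,Feteasca regala,Ni,2.978
leaf/soil,Feteasca regala,Co,0.896
leaf/soil,Feteasca regala,As,1.685
leaf/soil,Feteasca regala,Cr,0.407
leaf/soil,Feteasca regala,Hg,2.099
leaf/soil,Riesling italian,Cu,0.079
leaf/soil,Riesling italian,Zn,0.159
leaf/soil,Riesling italian,Pb,0.081
leaf/soil,Riesling italian,Cd,0.619
leaf/soil,Riesling italian,Ni,0.522
leaf/soil,Riesling italian,Co,0.889
leaf/soil,Riesling italian,As,1.401
leaf/soil,Riesling italian,Cr,0.201
leaf/soil,Riesling italian,Hg,0.327
grape/soil,Feteasca alba,Cu,0.008
grape/soil,Feteasca alba,Zn,0.011
grape/soil,Feteasca alba,Pb,0.006
grape/soil,Feteasca alba,Cd,0.159
grape/soil,Feteasca alba,Ni,0.165
grape/soil,Feteasca alba,Co,0.215
grape/soil,Feteasca alba,As,0.48
grape/soil,Feteasca alba,Cr,0.153
grape/soil,Feteasca alba,Hg,0.568
grape/soil,Feteasca regala,Cu,0.01
grape/soil,Feteasca regala,Zn,0.01
grape/soil,Feteasca regala,Pb,0.005
grape/soil,Feteasca regala,Cd,0.15
grape/soil,Feteasca regala,Ni,0.214
grape/soil,Feteasca regala,Co,0.422
grape/soil,Feteasca regala,As,0.4
grape/soil,Feteasca regala,Cr,0.143
grape/soil,Feteasca regala,Hg,0.494
grape/soil,Riesling italian,Cu,0.009
grape/soil,Riesling italian,Zn,0.009
grape/soil,Riesling italian,Pb,0.005
grape/soil,Riesling italian,Cd,0.142
grape/soil,Riesling italian,Ni,0.12
grape/soil,Riesling italian,Co,0.474
grape/soil,Riesling italian,As,0.359
grape/soil,Riesling italian,Cr,0.157
grape/soil,Riesling italian,Hg,0.105
must/soil,Feteasca alba,Cu,0.022
must/soil,Feteasca alba,Zn,0.023
must/soil,Feteasca alba,Pb,0.001
must/soil,Feteasca alba,Cd,0.018
must/soil,Feteasca alba,Ni,0.094
must/soil,Feteasca alba,Co,0
must/soil,Feteasca alba,As,0.024
must/soil,Feteasca alba,Cr,0.693
must/soil,Feteasca alba,Hg,0.009
must/soil,Feteasca regala,Cu,0.019
must/soil,Feteasca regala,Zn,0.024
must/soil,Feteasca regala,Pb,0.001
must/soil,Feteasca regala,Cd,0.016
must/soil,Feteasca regala,Ni,0.069
must/soil,Feteasca regala,Co,0
must/soil,Feteasca regala,As,0.033
must/soil,Feteasca regala,Cr,0.705
must/soil,Feteasca regala,Hg,0.009
must/soil,Riesling italian,Cu,0.017
must/soil,Riesling italian,Zn,0.02
must/soil,Riesling italian,Pb,0.001
must/soil,Riesling italian,Cd,0.016
must/soil,Riesling italian,Ni,0.014
must/soil,Riesling italian,Co,0
must/soil,Riesling italian,As,0.032
must/soil,Riesling italian,Cr,0.653
must/soil,Riesling italian,Hg,0.002
wine/soil,Feteasca alba,Cu,0.001
wine/soil,Feteasca alba,Zn,0.007
wine/soil,Feteasca alba,Pb,0
wine/soil,Feteasca alba,Cd,0.007
wine/soil,Feteasca alba,Ni,0.008
wine/soil,Feteasca alba,Co,0
wine/soil,Feteasca alba,As,0.019
wine/soil,Feteasca alba,Cr,0.586
wine/soil,Feteasca alba,Hg,0.002
wine/soil,Feteasca regala,Cu,0.001
wine/soil,Feteasca regala,Zn,0.008
wine/soil,Feteasca regala,Pb,0
wine/soil,Feteasca regala,Cd,0.006
wine/soil,Feteasca regala,Ni,0.008
wine/soil,Feteasca regala,Co,0
wine/soil,Feteasca regala,As,0.019
wine/soil,Feteasca regala,Cr,0.578
wine/soil,Feteasca regala,Hg,0
wine/soil,Riesling italian,Cu,0.001
wine/soil,Riesling italian,Zn,0.007
wine/soil,Riesling italian,Pb,0
wine/soil,Riesling italian,Cd,0.003
wine/soil,Riesling italian,Ni,0.003
wine/soil,Riesling italian,Co,0
wine/soil,Riesling italian,As,0.019
wine/soil,Riesling italian,Cr,0.579
wine/soil,Riesling italian,Hg,0
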