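pair,variety,element,ratio
root/soil,Feteasca alba,Cu,0.41
root/soil,Feteasca alba,Zn,0.2
root/soil,Feteasca alba,Pb,0.05
root/soil,Feteasca alba,Cd,0.53
root/soil,Feteasca alba,Ni,1
root/soil,Feteasca alba,Co,1.3
root/soil,Feteasca alba,As,1.02
root/soil,Feteasca alba,Cr,2.68
root/soil,Feteasca alba,Hg,0.94
root/soil,Feteasca regala,Cu,0.42
root/soil,Feteasca regala,Zn,0.19
root/soil,Feteasca regala,Pb,0.05
root/soil,Feteasca regala,Cd,0.64
root/soil,Feteasca regala,Ni,0.99
root/soil,Feteasca regala,Co,2.9
root/soil,Feteasca regala,As,1.23
root/soil,Feteasca regala,Cr,3.46
root/soil,Feteasca regala,Hg,0.76
root/soil,Riesling italian,Cu,0.53
root/soil,Riesling italian,Zn,0.16
root/soil,Riesling italian,Pb,0.05
root/soil,Riesling italian,Cd,0.57
root/soil,Riesling italian,Ni,0.48
root/soil,Riesling italian,Co,2.32
root/soil,Riesling italian,As,1.64
root/soil,Riesling italian,Cr,2.57
root/soil,Riesling italian,Hg,0.1
cane/root,Feteasca alba,Cu,0.19
cane/root,Feteasca alba,Zn,0.86
cane/root,Feteasca alba,Pb,1.12
cane/root,Feteasca alba,Cd,1.85
cane/root,Feteasca alba,Ni,0.79
cane/root,Feteasca alba,Co,0.79
cane/root,Feteasca alba,As,0.74
cane/root,Feteasca alba,Cr,0.27
cane/root,Feteasca alba,Hg,1.13
cane/root,Feteasca regala,Cu,0.2
cane/root,Feteasca regala,Zn,0.99
cane/root,Feteasca regala,Pb,1.21
cane/root,Feteasca regala,Cd,1.7
cane/root,Feteasca regala,Ni,0.93
cane/root,Feteasca regala,Co,2.98
cane/root,Feteasca regala,As,0.56
cane/root,Feteasca regala,Cr,0.16
cane/root,Feteasca regala,Hg,1.57
cane/root,Riesling italian,Cu,0.16
cane/root,Riesling italian,Zn,1.2
cane/root,Riesling italian,Pb,1.15
cane/root,Riesling italian,Cd,1.65
cane/root,Riesling italian,Ni,1.65
cane/root,Riesling italian,Co,3.07
cane/root,Riesling italian,As,0.57
cane/root,Riesling italian,Cr,0.25
cane/root,Riesling italian,Hg,1.53
leaf/cane,Feteasca alba,Cu,1.06
leaf/cane,Feteasca alba,Zn,0.94
leaf/cane,Feteasca alba,Pb,1.24
leaf/cane,Feteasca alba,Cd,0.64
leaf/cane,Feteasca alba,Ni,3.81
leaf/cane,Feteasca alba,Co,3.81
leaf/cane,Feteasca alba,As,2.73
leaf/cane,Feteasca alba,Cr,0.5
leaf/cane,Feteasca alba,Hg,2
leaf/cane,Feteasca regala,Cu,0.96
leaf/cane,Feteasca regala,Zn,0.79
leaf/cane,Feteasca regala,Pb,1.05
leaf/cane,Feteasca regala,Cd,0.74
leaf/cane,Feteasca regala,Ni,3.23
leaf/cane,Feteasca regala,Co,0.1
leaf/cane,Feteasca regala,As,2.46
leaf/cane,Feteasca regala,Cr,0.72
leaf/cane,Feteasca regala,Hg,1.76
leaf/cane,Riesling italian,Cu,0.94
leaf/cane,Riesling italian,Zn,0.85
leaf/cane,Riesling italian,Pb,1.38
leaf/cane,Riesling italian,Cd,0.66
leaf/cane,Riesling italian,Ni,0.66
leaf/cane,Riesling italian,Co,0.12
leaf/cane,Riesling italian,As,1.5
leaf/cane,Riesling italian,Cr,0.31
leaf/cane,Riesling italian,Hg,2.04
grape/cane,Feteasca alba,Cu,0.1
grape/cane,Feteasca alba,Zn,0.06
grape/cane,Feteasca alba,Pb,0.1
grape/cane,Feteasca alba,Cd,0.16
grape/cane,Feteasca alba,Ni,0.21
grape/cane,Feteasca alba,Co,0.21
grape/cane,Feteasca alba,As,0.63
grape/cane,Feteasca alba,Cr,0.21
grape/cane,Feteasca alba,Hg,0.53
grape/cane,Feteasca regala,Cu,0.12
grape/cane,Feteasca regala,Zn,0.05
grape/cane,Feteasca regala,Pb,0.08
grape/cane,Feteasca regala,Cd,0.14
grape/cane,Feteasca regala,Ni,0.23
grape/cane,Feteasca regala,Co,0.05
grape/cane,Feteasca regala,As,0.58
grape/cane,Feteasca regala,Cr,0.25
grape/cane,Feteasca regala,Hg,0.41
grape/cane,Riesling italian,Cu,0.11
grape/cane,Riesling italian,Zn,0.05
grape/cane,Riesling italian,Pb,0.08
grape/cane,Riesling italian,Cd,0.15
grape/cane,Riesling italian,Ni,0.15
grape/cane,Riesling italian,Co,0.07
grape/cane,Riesling italian,As,0.38
grape/cane,Riesling italian,Cr,0.24
grape/cane,Riesling italian,Hg,0.65
must/grape,Feteasca alba,Cu,2.78
must/grape,Feteasca alba,Zn,2.18
must/grape,Feteasca alba,Pb,0.1
must/grape,Feteasca alba,Cd,0.11
must/grape,Feteasca alba,Ni,0.57
must/grape,Feteasca alba,Co,0
must/grape,Feteasca alba,As,0.05
must/grape,Feteasca alba,Cr,4.52
must/grape,Feteasca alba,Hg,0.02
must/grape,Feteasca regala,Cu,1.94
must/grape,Feteasca regala,Zn,2.41
must/grape,Feteasca regala,Pb,0.14
must/grape,Feteasca regala,Cd,0.11
must/grape,Feteasca regala,Ni,0.32
must/grape,Feteasca regala,Co,0
must/grape,Feteasca regala,As,0.08
must/grape,Feteasca regala,Cr,4.93
must/grape,Feteasca regala,Hg,0.02
must/grape,Riesling italian,Cu,1.84
must/grape,Riesling italian,Zn,2.24
must/grape,Riesling italian,Pb,0.15
must/grape,Riesling italian,Cd,0.11
must/grape,Riesling italian,Ni,0.11
must/grape,Riesling italian,Co,0
must/grape,Riesling italian,As,0.09
must/grape,Riesling italian,Cr,4.16
must/grape,Riesling italian,Hg,0.02
wine/must,Feteasca alba,Cu,0.07
wine/must,Feteasca alba,Zn,0.3
wine/must,Feteasca alba,Pb,0.33
wine/must,Feteasca alba,Cd,0.38
wine/must,Feteasca alba,Ni,0.09
wine/must,Feteasca alba,Co,0.09
wine/must,Feteasca alba,As,0.79
wine/must,Feteasca alba,Cr,0.85
wine/must,Feteasca alba,Hg,0.23
wine/must,Feteasca regala,Cu,0.06
wine/must,Feteasca regala,Zn,0.35
wine/must,Feteasca regala,Pb,0.35
wine/must,Feteasca regala,Cd,0.39
wine/must,Feteasca regala,Ni,0.12
wine/must,Feteasca regala,Co,0
wine/must,Feteasca regala,As,0.58
wine/must,Feteasca regala,Cr,0.82
wine/must,Feteasca regala,Hg,0
wine/must,Riesling italian,Cu,0.06
wine/must,Riesling italian,Zn,0.35
wine/must,Riesling italian,Pb,0.22
wine/must,Riesling italian,Cd,0.22
wine/must,Riesling italian,Ni,0.22
wine/must,Riesling italian,Co,0
wine/must,Riesling italian,As,0.6
wine/must,Riesling italian,Cr,0.89
wine/must,Riesling italian,Hg,0
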