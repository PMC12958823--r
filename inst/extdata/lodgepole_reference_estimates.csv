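model,approach,trait,additive,residual,heritability
MTM,ABLUP,HT,0.69,0.28,0.71
MTM,ABLUP,WGR,0.58,0.49,0.54
MTM,ABLUP,WD,0.62,0.43,0.59
MTM,ABLUP,RES,0.43,0.63,0.40
MTM,ABLUP,DECL,0.54,0.59,0.47
MTM,ABLUP,C13,0.64,0.38,0.63
MTM,ABLUP,LIMO,0.40,0.65,0.38
MTM,ABLUP,T_MONO,0.31,0.72,0.30
MTM,ABLUP,CAR,0.27,0.79,0.25
MTM,GBLUP,HT,0.48,0.47,0.50
MTM,GBLUP,WGR,0.68,0.40,0.63
MTM,GBLUP,WD,0.60,0.44,0.58
MTM,GBLUP,RES,0.30,0.75,0.28
MTM,GBLUP,DECL,0.41,0.70,0.37
MTM,GBLUP,C13,0.53,0.48,0.52
MTM,GBLUP,LIMO,0.33,0.73,0.31
MTM,GBLUP,T_MONO,0.29,0.73,0.28
MTM,GBLUP,CAR,0.25,0.80,0.24
SEM,ABLUP,HT,0.59,0.35,0.63
SEM,ABLUP,WGR,0.75,0.36,0.67
SEM,ABLUP,WD,0.84,0.25,0.77
SEM,ABLUP,RES,0.47,0.60,0.43
SEM,ABLUP,DECL,0.43,0.68,0.38
SEM,ABLUP,C13,0.85,0.21,0.80
SEM,ABLUP,LIMO,0.54,0.54,0.49
SEM,ABLUP,T_MONO,0.43,0.63,0.40
SEM,ABLUP,CAR,0.61,0.54,0.52
SEM,GBLUP,HT,0.51,0.44,0.53
SEM,GBLUP,WGR,0.74,0.36,0.67
SEM,GBLUP,WD,0.80,0.28,0.74
SEM,GBLUP,RES,0.44,0.62,0.42
SEM,GBLUP,DECL,0.48,0.62,0.44
SEM,GBLUP,C13,0.72,0.34,0.68
SEM,GBLUP,LIMO,0.38,0.67,0.36
SEM,GBLUP,T_MONO,0.39,0.65,0.37
SEM,GBLUP,CAR,0.49,0.63,0.43
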