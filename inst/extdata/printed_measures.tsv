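classifier	scope	measure	printed
lda	SAM-IV	accuracy	99.09
lda	glycine	accuracy	83.63
lda	glycine	sensitivity	100
lda	cyclic-di-GMP-I	sensitivity	66.45
lda	cyclic-di-GMP-I	specificity	99.82
lda	glycine	specificity	82.66
lda	SAM-IV	f_score	92.31
lda	glycine	f_score	40.74
pnn	SAM-IV	accuracy	99.33
pnn	SAH	accuracy	87.66
pnn	cobalamin	sensitivity	94.65
pnn	SAH	sensitivity	48
pnn	SAM-IV	specificity	99.72
pnn	SAH	specificity	92.94
pnn	cobalamin	f_score	96.56
pnn	SAH	f_score	47.76
tree	SAM-alpha	accuracy	97.93
tree	SAH	accuracy	88.07
tree	cobalamin	sensitivity	93.49
tree	SAH	sensitivity	44.09
tree	SAM-alpha	specificity	99.27
tree	cobalamin	specificity	93.31
tree	cobalamin	f_score	94.15
tree	SAH	f_score	46.07
knn	SAM-IV	accuracy	99.03
knn	SAH	accuracy	87.67
knn	cobalamin	sensitivity	94.42
knn	SAH	sensitivity	44.09
knn	SAM-IV	specificity	100
knn	cobalamin	specificity	89.14
knn	cobalamin	f_score	92.91
knn	SAH	f_score	44.81
pnn	macro	accuracy	96.1
knn	macro	accuracy	95.2
tree	macro	accuracy	94.79
lda	macro	accuracy	93.98
pnn	macro	sensitivity	83.61
lda	macro	sensitivity	82.3
tree	macro	sensitivity	76.81
knn	macro	sensitivity	76.76
pnn	macro	specificity	97.69
lda	macro	specificity	96.9
tree	macro	specificity	96.58
knn	macro	specificity	96.53
pnn	macro	f_score	81.91
knn	macro	f_score	78.44
lda	macro	f_score	77.97
tree	macro	f_score	74.9
pnn	ccr	ccr	92.31
tree	ccr	ccr	89.37
knn	ccr	ccr	88.86
lda	ccr	ccr	80.94
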