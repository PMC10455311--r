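# Published per-class confusion counts for a 190-variant blind test of a
# three-class folding-rate-effect classifier, for the full 1161-feature model
# and the 31-selected-feature model.  Classes: decrease / no_effect / increase.
feature_set	class	TP	TN	FP	FN
all	decrease	65	33	24	68
all	no_effect	11	118	33	28
all	increase	8	123	49	10
selected31	decrease	60	32	25	73
selected31	no_effect	10	110	41	29
selected31	increase	7	125	47	11
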