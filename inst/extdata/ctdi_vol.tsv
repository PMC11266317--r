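# CTDI_vol fixture for the studied (kVp, QRM) combinations, mGy.
# source = printed: value reported for this setting; interpolated: filled by
# linear-in-mAs scaling from the same-kVp printed anchor.
# columns: kvp	qrm	ctdi_mgy	source
kvp	qrm	ctdi_mgy	source
80	20	0.9	printed
80	35	1.6	interpolated
80	50	2.3	interpolated
110	20	1.5	printed
110	35	2.6	interpolated
130	20	2.0	printed
130	35	3.6	printed
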