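polymorphism,study_id,hwe_p
4b/a,b95,0.099
4b/a,b62,0.152
4b/a,b57,0.342
4b/a,b38,0.535
4b/a,b3,0.31
4b/a,b27,0.655
4b/a,b44,0.78
4b/a,b34,0.58
4b/a,b37,0.386
4b/a,b45,0
4b/a,b92,0.468
4b/a,b47,0.323
4b/a,b73,0.32
4b/a,b14,0.167
4b/a,b91,0.734
4b/a,b83,0.487
4b/a,b68,0.056
4b/a,b10,0.079
4b/a,b87,0.218
4b/a,b18,0.594
4b/a,b21,0.25
4b/a,b33,0.169
4b/a,b11,0
4b/a,b89,0.433
4b/a,b32,0.28
4b/a,b4,0.107
4b/a,b42,0.057
4b/a,b51,0.373
4b/a,b69,0.871
4b/a,b23,0
4b/a,b63,0.106
4b/a,b70,0.768
4b/a,b88,0.068
4b/a,b1,0.84
4b/a,b64_1,0.217
4b/a,b64_2,0.036
g894t,b62,0.72
g894t,b74,0.016
g894t,b79,0.883
g894t,b38,0.606
g894t,b60,0.753
g894t,b58,0.096
g894t,b55,0.199
g894t,b56,0.016
g894t,b65,0.188
g894t,b71,0.547
g894t,b14,0.606
g894t,b68,0.138
g894t,b10,0.146
g894t,b94,0.394
g894t,b46,0.351
g894t,b20,0.403
g894t,b48,0.452
g894t,b18,0.274
g894t,b66,0.001
g894t,b76,0.845
g894t,b59,0.58
g894t,b75,0.162
g894t,b11,0
g894t,b32,0.135
g894t,b8,0.549
g894t,b4,0.29
g894t,b17,0.987
g894t,b2,0.029
g894t,b69,0.098
g894t,b43,0.659
g894t,b26,0.998
g894t,b9,0.201
g894t,b6_1,0.998
g894t,b6_2,0.676
g894t,b29,0.273
g894t,b49,0.576
g894t,b41,0.074
g894t,b54,0.002
g894t,b52,0.004
g894t,b67,0.015
g894t,b1,0.516
g894t,b64_1,0.115
g894t,b64_2,0.696
g894t,b24,0.98
t786c,b60,0.115
t786c,b68,0.361
t786c,b10,0.314
t786c,b18,0.623
t786c,b32,0.301
t786c,b4,0.123
t786c,b69,0.913
t786c,b41,0.653
t786c,b25,0.146
t786c,b52,0
t786c,b1,0.277
t786c,b64_1,0.215
t786c,b64_2,0.782
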