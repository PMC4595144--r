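GENE00005
GENE00010
GENE00015
GENE00020
GENE00025
GENE00030
GENE00035
GENE00040
GENE00045
GENE00050
GENE00055
GENE00060
GENE00065
GENE00070
GENE00075
GENE00080
GENE00085
GENE00090
GENE00095
GENE00100
GENE00105
GENE00110
GENE00115
GENE00120
GENE00125
GENE00130
GENE00135
GENE00140
GENE00145
GENE00150
GENE00155
GENE00160
GENE00165
GENE00170
GENE00175
GENE00180
GENE00185
GENE00190
GENE00195
GENE00200
GENE00205
GENE00210
GENE00215
GENE00220
GENE00225
GENE00230
GENE00235
GENE00240
GENE00245
GENE00250
GENE00255
GENE00260
GENE00265
GENE00270
GENE00275
GENE00280
GENE00285
GENE00290
GENE00295
GENE00300
GENE00305
GENE00310
GENE00315
GENE00320
GENE00325
GENE00330
GENE00335
GENE00340
GENE00345
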