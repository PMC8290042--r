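place_id,user_count
C01,88
C02,52
C03,61
C04,59
C05,99
C06,51
C07,103
C08,146
C09,66
C10,129
C11,103
C12,107
C13,120
C14,101
C15,66
C16,119
C17,134
C18,68
C19,84
C20,75
C21,120
C22,81
C23,26
C24,44
C25,126
C26,120
C27,52
C28,74
C29,19
C30,94
C31,97
C32,57
C33,85
C34,14
C35,71
C36,78
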