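place_id,k,label
C01,9,0
C07,9,0
C08,9,0
C13,9,0
C14,9,0
C02,9,0
C03,9,0
C04,9,1
C05,9,1
C11,9,1
C10,9,1
C12,9,1
C16,9,1
C17,9,1
C18,9,1
C06,9,1
C09,9,2
C15,9,2
C19,9,3
C21,9,3
C25,9,3
C31,9,3
C26,9,3
C32,9,3
C33,9,3
C20,9,3
C22,9,4
C28,9,4
C30,9,4
C36,9,4
C35,9,4
C23,9,5
C24,9,5
C27,9,6
C29,9,7
C34,9,8
C01,4,0
C07,4,0
C08,4,0
C13,4,0
C14,4,0
C02,4,0
C03,4,0
C09,4,0
C15,4,0
C04,4,1
C05,4,1
C11,4,1
C10,4,1
C12,4,1
C16,4,1
C17,4,1
C18,4,1
C06,4,1
C19,4,2
C21,4,2
C25,4,2
C31,4,2
C26,4,2
C32,4,2
C33,4,2
C20,4,2
C27,4,2
C22,4,3
C28,4,3
C30,4,3
C36,4,3
C35,4,3
C23,4,3
C24,4,3
C29,4,3
C34,4,3
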