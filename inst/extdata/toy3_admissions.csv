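residence_unit,hospital_unit,diagnosis_group,year
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,A,XV,2012
A,B,XV,2012
A,B,XV,2012
A,B,XV,2012
A,B,XV,2012
A,B,XV,2012
A,B,XV,2012
A,B,XV,2012
A,B,XV,2012
A,B,XV,2012
A,B,XV,2012
A,B,XV,2012
A,B,XV,2012
A,B,XV,2012
A,B,XV,2012
A,B,XV,2012
A,B,XV,2012
A,B,XV,2012
A,B,XV,2012
A,B,XV,2012
A,B,XV,2012
A,B,XV,2012
A,B,XV,2012
A,B,XV,2012
A,B,XV,2012
A,B,XV,2012
A,B,XV,2012
A,B,XV,2012
A,B,XV,2012
A,B,XV,2012
A,B,XV,2012
A,B,XV,2012
A,B,XV,2012
A,B,XV,2012
A,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
B,B,XV,2012
C,B,XV,2012
C,B,XV,2012
C,B,XV,2012
C,B,XV,2012
C,B,XV,2012
C,B,XV,2012
C,B,XV,2012
C,B,XV,2012
C,B,XV,2012
C,B,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
C,C,XV,2012
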