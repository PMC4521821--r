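Tmeanday	Tmaxday	Insday	RHday	Plday	sugar	acidity
high	high	high	high	high	0	0
high	high	high	high	low	1	1
high	high	high	high	middleminus	1	1
high	high	high	high	middleplus	1	1
high	high	high	low	high	0	0
high	high	high	low	low	1	1
high	high	high	low	middleminus	1	1
high	high	high	low	middleplus	1	1
high	high	low	high	high	0	0
high	high	low	high	low	1	1
high	high	low	high	middleminus	1	1
high	high	low	high	middleplus	0	0
high	high	low	low	high	0	0
high	high	low	low	low	1	1
high	high	low	low	middleminus	1	1
high	high	low	low	middleplus	0	0
high	high	middle	high	high	0	0
high	high	middle	high	low	1	1
high	high	middle	high	middleminus	1	1
high	high	middle	high	middleplus	1	1
high	high	middle	low	high	0	0
high	high	middle	low	low	1	1
high	high	middle	low	middleminus	1	1
high	high	middle	low	middleplus	1	1
high	low	high	high	high	1	1
high	low	high	high	low	3	3
high	low	high	high	middleminus	2	2
high	low	high	high	middleplus	1	1
high	low	high	low	high	1	1
high	low	high	low	low	3	3
high	low	high	low	middleminus	2	2
high	low	high	low	middleplus	1	1
high	low	low	high	high	1	1
high	low	low	high	low	2	2
high	low	low	high	middleminus	1	1
high	low	low	high	middleplus	1	1
high	low	low	low	high	1	1
high	low	low	low	low	2	2
high	low	low	low	middleminus	1	1
high	low	low	low	middleplus	1	1
high	low	middle	high	high	1	1
high	low	middle	high	low	3	3
high	low	middle	high	middleminus	2	2
high	low	middle	high	middleplus	1	1
high	low	middle	low	high	1	1
high	low	middle	low	low	3	3
high	low	middle	low	middleminus	2	2
high	low	middle	low	middleplus	1	1
high	middle	high	high	high	1	1
high	middle	high	high	low	2	2
high	middle	high	high	middleminus	2	2
high	middle	high	high	middleplus	1	1
high	middle	high	low	high	1	1
high	middle	high	low	low	2	2
high	middle	high	low	middleminus	2	2
high	middle	high	low	middleplus	1	1
high	middle	low	high	high	0	0
high	middle	low	high	low	1	1
high	middle	low	high	middleminus	1	1
high	middle	low	high	middleplus	1	1
high	middle	low	low	high	0	0
high	middle	low	low	low	1	1
high	middle	low	low	middleminus	1	1
high	middle	low	low	middleplus	1	1
high	middle	middle	high	high	1	1
high	middle	middle	high	low	2	2
high	middle	middle	high	middleminus	2	2
high	middle	middle	high	middleplus	1	1
high	middle	middle	low	high	1	1
high	middle	middle	low	low	2	2
high	middle	middle	low	middleminus	2	2
high	middle	middle	low	middleplus	1	1
low	high	high	high	high	0	0
low	high	high	high	low	0	0
low	high	high	high	middleminus	0	0
low	high	high	high	middleplus	0	0
low	high	high	low	high	0	0
low	high	high	low	low	0	0
low	high	high	low	middleminus	0	0
low	high	high	low	middleplus	0	0
low	high	low	high	high	0	0
low	high	low	high	low	0	0
low	high	low	high	middleminus	0	0
low	high	low	high	middleplus	0	0
low	high	low	low	high	0	0
low	high	low	low	low	0	0
low	high	low	low	middleminus	0	0
low	high	low	low	middleplus	0	0
low	high	middle	high	high	0	0
low	high	middle	high	low	0	0
low	high	middle	high	middleminus	0	0
low	high	middle	high	middleplus	0	0
low	high	middle	low	high	0	0
low	high	middle	low	low	0	0
low	high	middle	low	middleminus	0	0
low	high	middle	low	middleplus	0	0
low	low	high	high	high	0	0
low	low	high	high	low	1	1
low	low	high	high	middleminus	1	1
low	low	high	high	middleplus	1	1
low	low	high	low	high	0	0
low	low	high	low	low	1	1
low	low	high	low	middleminus	1	1
low	low	high	low	middleplus	1	1
low	low	low	high	high	0	0
low	low	low	high	low	1	1
low	low	low	high	middleminus	1	1
low	low	low	high	middleplus	0	0
low	low	low	low	high	0	0
low	low	low	low	low	1	1
low	low	low	low	middleminus	1	1
low	low	low	low	middleplus	0	0
low	low	middle	high	high	0	0
low	low	middle	high	low	1	1
low	low	middle	high	middleminus	1	1
low	low	middle	high	middleplus	1	1
low	low	middle	low	high	0	0
low	low	middle	low	low	1	1
low	low	middle	low	middleminus	1	1
low	low	middle	low	middleplus	1	1
low	middle	high	high	high	0	0
low	middle	high	high	low	1	1
low	middle	high	high	middleminus	1	1
low	middle	high	high	middleplus	0	0
low	middle	high	low	high	0	0
low	middle	high	low	low	1	1
low	middle	high	low	middleminus	1	1
low	middle	high	low	middleplus	0	0
low	middle	low	high	high	0	0
low	middle	low	high	low	1	1
low	middle	low	high	middleminus	0	0
low	middle	low	high	middleplus	0	0
low	middle	low	low	high	0	0
low	middle	low	low	low	1	1
low	middle	low	low	middleminus	0	0
low	middle	low	low	middleplus	0	0
low	middle	middle	high	high	0	0
low	middle	middle	high	low	1	1
low	middle	middle	high	middleminus	1	1
low	middle	middle	high	middleplus	0	0
low	middle	middle	low	high	0	0
low	middle	middle	low	low	1	1
low	middle	middle	low	middleminus	1	1
low	middle	middle	low	middleplus	0	0
middle	high	high	high	high	0	0
middle	high	high	high	low	1	1
middle	high	high	high	middleminus	1	1
middle	high	high	high	middleplus	1	1
middle	high	high	low	high	0	0
middle	high	high	low	low	1	1
middle	high	high	low	middleminus	1	1
middle	high	high	low	middleplus	1	1
middle	high	low	high	high	0	0
middle	high	low	high	low	1	1
middle	high	low	high	middleminus	1	1
middle	high	low	high	middleplus	0	0
middle	high	low	low	high	0	0
middle	high	low	low	low	1	1
middle	high	low	low	middleminus	1	1
middle	high	low	low	middleplus	0	0
middle	high	middle	high	high	0	0
middle	high	middle	high	low	1	1
middle	high	middle	high	middleminus	1	1
middle	high	middle	high	middleplus	1	1
middle	high	middle	low	high	0	0
middle	high	middle	low	low	1	1
middle	high	middle	low	middleminus	1	1
middle	high	middle	low	middleplus	1	1
middle	low	high	high	high	1	1
middle	low	high	high	low	2	2
middle	low	high	high	middleminus	2	2
middle	low	high	high	middleplus	1	1
middle	low	high	low	high	1	1
middle	low	high	low	low	2	2
middle	low	high	low	middleminus	2	2
middle	low	high	low	middleplus	1	1
middle	low	low	high	high	0	0
middle	low	low	high	low	1	1
middle	low	low	high	middleminus	1	1
middle	low	low	high	middleplus	1	1
middle	low	low	low	high	0	0
middle	low	low	low	low	1	1
middle	low	low	low	middleminus	1	1
middle	low	low	low	middleplus	1	1
middle	low	middle	high	high	1	1
middle	low	middle	high	low	2	2
middle	low	middle	high	middleminus	2	2
middle	low	middle	high	middleplus	1	1
middle	low	middle	low	high	1	1
middle	low	middle	low	low	2	2
middle	low	middle	low	middleminus	2	2
middle	low	middle	low	middleplus	1	1
middle	middle	high	high	high	1	1
middle	middle	high	high	low	2	2
middle	middle	high	high	middleminus	1	1
middle	middle	high	high	middleplus	1	1
middle	middle	high	low	high	1	1
middle	middle	high	low	low	2	2
middle	middle	high	low	middleminus	1	1
middle	middle	high	low	middleplus	1	1
middle	middle	low	high	high	0	0
middle	middle	low	high	low	1	1
middle	middle	low	high	middleminus	1	1
middle	middle	low	high	middleplus	1	1
middle	middle	low	low	high	0	0
middle	middle	low	low	low	1	1
middle	middle	low	low	middleminus	1	1
middle	middle	low	low	middleplus	1	1
middle	middle	middle	high	high	1	1
middle	middle	middle	high	low	2	2
middle	middle	middle	high	middleminus	1	1
middle	middle	middle	high	middleplus	1	1
middle	middle	middle	low	high	1	1
middle	middle	middle	low	low	2	2
middle	middle	middle	low	middleminus	1	1
middle	middle	middle	low	middleplus	1	1
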