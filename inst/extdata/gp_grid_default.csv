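sex,age_months
male,6
male,9
male,12
male,18
male,24
male,30
male,36
male,42
male,48
male,54
male,60
male,72
male,84
male,96
male,108
male,120
male,126
male,132
male,138
male,144
male,150
male,156
male,162
male,168
male,180
male,192
male,204
male,216
male,228
female,6
female,9
female,12
female,18
female,24
female,30
female,36
female,42
female,48
female,54
female,60
female,72
female,84
female,96
female,108
female,114
female,120
female,126
female,132
female,138
female,144
female,150
female,156
female,162
female,174
female,186
female,198
female,216
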