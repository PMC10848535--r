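sex,age_band,le_index,le_ref,led_index,led_ref,eln_index,eln_ref
male,25-34,28.7,47.9,11.6,24.0,151637,387970
male,35-40,19.7,40.9,8.1,18.1,109220,297409
male,41-45,14.7,35.8,6.2,14.0,77449,225214
male,46-50,11.3,31.7,4.9,10.4,58314,163907
male,51-55,9.6,27.5,3.6,6.9,42222,106023
male,56-60,7.9,23.5,2.0,3.5,23188,51958
male,61-64,7.0,19.9,0.7,1.0,7777,13949
female,25-34,31.5,54.0,10.7,23.5,120035,311230
female,35-40,25.1,46.6,9.8,17.6,107202,230081
female,41-45,19.1,41.4,7.8,13.5,81621,171502
female,46-50,16.0,36.7,6.1,9.8,61464,119905
female,51-55,12.1,32.1,4.0,6.2,39243,73917
female,56-60,9.6,27.4,2.0,3.0,19361,33474
female,61-64,7.6,23.3,0.6,0.8,5685,8391
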