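id	equation	ec
R00005	C01010 + C00001 <=> 2 C00011 + 2 C00014	3.5.1.54
R00260	C00025 <=> C00217	5.1.1.3
R00683	C00019 + C00078 <=> C00021 + C00643	
R02910	C00019 + C00780 <=> C00021 + C02718	2.1.1.49
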