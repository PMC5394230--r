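label,ai,mass_factor
glyphosate,glyphosate,1
glyphosate isopropylamine salt,glyphosate,1
glyphosate potassium salt,glyphosate,1
glyphosate ammonium salt,glyphosate,1
glyphosate diammonium salt,glyphosate,1
glyphosate dimethylamine salt,glyphosate,1
glyphosate monoammonium salt,glyphosate,1
glyphosate trimesium,glyphosate,1
"2,4-d","2,4-d",1
"2,4-d dimethylamine salt","2,4-d",1
"2,4-d 2-ethylhexyl ester","2,4-d",1
"2,4-d butoxyethyl ester","2,4-d",1
"2,4-d isooctyl ester","2,4-d",1
"2,4-d diethanolamine salt","2,4-d",1
"2,4-d triisopropanolamine salt","2,4-d",1
"2,4-d sodium salt","2,4-d",1
"2,4-d isopropylamine salt","2,4-d",1
dicamba,dicamba,1
dicamba diglycolamine salt,dicamba,1
dicamba dimethylamine salt,dicamba,1
dicamba sodium salt,dicamba,1
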