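Basic	Field	Greenhouse
Source Name	Source Name	Source Name
Characteristics[Organism]	Characteristics[Organism]	Characteristics[Organism]
Characteristics[Infraspecific name]	Characteristics[Infraspecific name]	Characteristics[Infraspecific name]
Characteristics[Seed origin]	Characteristics[Seed origin]	Characteristics[Seed origin]
Characteristics[Study start]	Characteristics[Study start]	Characteristics[Study start]
Characteristics[Study duration]	Characteristics[Study duration]	Characteristics[Study duration]
Characteristics[Growth facility]	Characteristics[Growth facility]	Characteristics[Growth facility]
Characteristics[Geographic location]	Characteristics[Geographic location]	Characteristics[Geographic location]
	Protocol REF[Rooting]	Protocol REF[Rooting]
	Parameter Value[Rooting medium]	Parameter Value[Rooting medium]
		Parameter Value[Container type]
		Parameter Value[Container volume]
	Parameter Value[Plot size]	Parameter Value[Container dimension]
	Unit	Unit
	Parameter Value[Sowing density]	Parameter Value[Number of plants per container]
	Parameter Value[pH]	Parameter Value[pH]
	Protocol REF[Aerial conditions]	Protocol REF[Aerial conditions]
	Parameter Value[Air humidity]	Parameter Value[Air humidity]
	Parameter Value[Daily photon flux]	Parameter Value[Daily photon flux]
	Parameter Value[Length of light period]	Parameter Value[Length of light period]
	Parameter Value[Day temperature]	Parameter Value[Day temperature]
	Parameter Value[Night temperature]	Parameter Value[Night temperature]
	Protocol REF[Nutrition]	Protocol REF[Nutrition]
	Parameter Value[N before fertilisation]	Parameter Value[N before fertilisation]
	Parameter Value[Type of fertiliser]	Parameter Value[Type of fertiliser]
	Parameter Value[Amount of fertiliser]	Parameter Value[Amount of fertiliser]
	Protocol REF[Watering]	Protocol REF[Watering]
	Parameter Value[Irrigation type]	Parameter Value[Irrigation type]
	Parameter Value[Volume]	Parameter Value[Volume]
	Parameter Value[Frequency]	Parameter Value[Frequency]
	Protocol REF[Sampling]	Protocol REF[Sampling]
	Parameter Value[Experimental unit]	Parameter Value[Experimental unit]
Sample Name	Sample Name	Sample Name
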