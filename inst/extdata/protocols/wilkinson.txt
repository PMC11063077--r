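[File_Input_Selection, Simple_Optimization, Central_Metal_Selection, Dissociation, All_Compounds_Selection, Association, All_Compounds_Selection, Association, Products_Selection, Rearrangement, Products_Selection, Rearrangement, Products_Selection, Dissociation]
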