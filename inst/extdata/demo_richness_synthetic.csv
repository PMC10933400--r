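order,family,species_count
Order_01,Family_01_01,14
Order_01,Family_01_02,34
Order_01,Family_01_03,45
Order_02,Family_02_01,54
Order_02,Family_02_02,35
Order_02,Family_02_03,20
Order_03,Family_03_01,44
Order_03,Family_03_02,44
Order_03,Family_03_03,25
Order_04,Family_04_01,20
Order_04,Family_04_02,46
Order_04,Family_04_03,59
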