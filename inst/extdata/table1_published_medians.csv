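level,unit,parent,year,median
region,Adamawa,national,2000,137484
region,Adamawa,national,2010,184659
region,Adamawa,national,2020,252072
region,Adamawa,national,2030,348829
region,Centre,national,2000,337354
region,Centre,national,2010,504928
region,Centre,national,2020,786405
region,Centre,national,2030,1264514
region,East,national,2000,109582
region,East,national,2010,134833
region,East,national,2020,167296
region,East,national,2030,208402
region,Far North,national,2000,495044
region,Far North,national,2010,633579
region,Far North,national,2020,818946
region,Far North,national,2030,1069814
region,Littoral,national,2000,283893
region,Littoral,national,2010,400442
region,Littoral,national,2020,576482
region,Littoral,national,2030,841799
region,North,national,2000,272069
region,North,national,2010,419150
region,North,national,2020,662131
region,North,national,2030,1066891
region,Northwest,national,2000,164941
region,Northwest,national,2010,206518
region,Northwest,national,2020,265193
region,Northwest,national,2030,350104
region,West,national,2000,227774
region,West,national,2010,266688
region,West,national,2020,321025
region,West,national,2030,396079
region,South,national,2000,74957
region,South,national,2010,110865
region,South,national,2020,167628
region,South,national,2030,258435
region,Southwest,national,2000,157567
region,Southwest,national,2010,194928
region,Southwest,national,2020,247275
region,Southwest,national,2030,319614
national,national,,2000,2260665
national,national,,2010,3056589
national,national,,2020,4264453
national,national,,2030,6124480
division,Mfoundi,Centre,2030,1019032
division,Wouri,Littoral,2030,749306
division,Benoue,North,2030,706967
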