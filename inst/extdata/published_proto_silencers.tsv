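# Printed coordinate pairs of Rap1/Abf1 binding-site matches co-occurring
# within 50 bp in S. cerevisiae euchromatic intergenic regions
# (site map of MacIsaac et al. 2006).
chromosome	rap1_position	abf1_position
I	141851	141829
II	682048	682084
IV	43804	43828
IV	836178	836216
V	491217	491253
VI	58434	58387
VII	197190	197205
IX	254357	254318
X	651339	651294
X	684313	684307
XI	39028	39012
XI	327627	327609
XI	407935	407972
XI	416723	416684
XII	202816	202847
XII	636493	636519
XII	1064491	1064536
XIII	551528	551491
XIV	57801	57820
XIV	355971	355965
XV	216461	216412
XV	274433	274471
XV	780709	780747
XV	1009784	1009821
XVI	866585	866602
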