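>SYN00001_1|species_00001
LMPSRACFRPHIMIFNNGYEKMQTYPYRGGYHYDQGKTWPDQDAHKQSGTSNNLPIQGHL
VMCEPLSWFHPAGYYHCLFAPTHPWFQPCNLCCSYYCISDIPYQNIVLDEWNPTHNNNKS
PWEMTNAMTPDEDRNSRNDKCLWSIRRYEQTVTHHPLTAIKNVLNHDMMYLCGTVKTVEC
VYTIGQWWYRRCDKFTPAMTEYFMFVEFDIPHVSGCKMCEICLWPTNRWDGGSGGNPLST
DAMKDQHAHVKKERNVDAWIPKFTDVPWHRFEGKRSYYCREPHLLNPRMSLCNVNFPCDA
WAKTPISEHCKQHTQTAPIAMGVNNAINQSGNLQFLAHGLIHADEDENTFFIPSPNRMEH
RPPEDIKQTFFTDVARKPPCHCDKWPWMMEDSQDDVASNT
>SYN00002_1|species_00002
LMNSRACWHPFNMIFNNGKEIMQTYKYRGGYHYDQGKTWPDCFAHKQSGTSQNLPIQGHT
VMLEPVSWFHVAGYYNCLGAPTHPWFQPFWLCGSYNCISDIPYTNIVLDEWNPCPNNNKG
RCEMTNAMTPDEDRNSRNDPCLQSIRRYPQTVTAHPLTACKNPLNHDFMYLNQIVTTIEQ
VYTRGQGMYRRCDKFTQAMTEYIMFNEFDIPHISGCKMCEICLAPTGRWDGGTGGNPLST
DSMYDQHAHVSKEHYLDAWIPKFTDVPWSIQHGKRSYYCREPHLLNWDMSLCQWNFPHDA
WRKTPISDHCKQHTQTVPIAMGVNNAINQSGNLHFLAWGLIHAEEDENTFFMPSPVRMEY
RPPEDIKQTDFTDVARKPPCDCDKWPWHMEDSQDDVASNTGGSMGQVYVGWNIECIRDVY
WTTERGDRPQHGWCIDHNCAWTELGYWAWWGAYSAGDGCNSVVELQEYHMMVCQALPHQY
NFDKCHSACRVKRYGCVTITTWCVIDTIAQGGSGGHQYHARYWNVLRMYETSCFDQDQFS
QQQNKWGVGSRRSKPDATVHEPDYDRFWSRVRDDDQDLPYLYSRDTNPMEEEKVSNETPC
FCKKDNVMEQAYRTVPAAENYMATISFLRCSYEYVEQSTETMNHMITRVRTWIARKTSPF
WPCIMSVQWNQLNGFVFGGSGACRVRQHPGTRHLCFLNPNMKGWCWWASLMWFRVKSCQQ
WNSCTPHDRTCNNVQGLFHYQMQFKRHTEFNCEFLWVEYRGYGADEYRNWHFQVKNNCQS
LATCFPLCMRKKQRYVFSMPPHVVCMAHVHRNYRFKLEAMSWLFTFFDCAMEVQEMHCSQ
EDYGGSDTWWAIHFYYSMIASIQHDWICPQCLDWAENEENMANICGECQCWQSYIHSARK
WPVSYKMWTWKVFY
>SYN00003_1|species_00003
LMISRACFRPFNMIFNNCKEIMQTYPYRGGYHYDQGKTWPDQFAHKQSGTSNNLPIQGHT
VMCEPQSWFHPAGYYNCLFAPTYEWAQPCWLIGSCNCISDSPYTNIVLDEWNPDPNNNKF
KWEMTNAMMPDEDRNSRNDPCLESIYRYWQTVTHHPLIACKNVLNLDMMYLCQIVITIEC
VYHRGQWNYRRCDKFTPAMTEYEMFVEFDIFHISGCKTCEICLAGTGHWDGGSGGNPLST
DSMYDQHAHVKKEHNLDAWIPKFTDVPWHMFHCSRSYICREFHLLNPDMSLCQVNFPHDA
WRKTPISEHAKQHNQTVPIAMGVNEAIGQSCNLQFLAHGLIRAEEDTNTFFIPSPVFMDY
RRPEDGKQTFFQDIARKPECMCDKWPMHLEDSQDEVASNTGGSGGQVYDGWNDETIMDVY
WTTERYDTTQHGWCKDHNCAWTELGYWAIWAAYSAGIGCNSVVEAQKYHMMVCQALPHQY
NFDKTHSACRVKRTFCVTIGAWCPIDTIAKGGSGGTVYHARYWNVLRMYETSCFDPDQFS
QSQVKWPVPSRRSKPDATVHWPDYDRFWSRVRDKDQDLPYLYSRDTNPMLEEKVKNETPC
QQMKDNVMQWCVRTVPAADNYMATITKLRCTYEYVWQSTETMNLMITRVRTWIARATSPF
WPCIMSVQWNQLNGFCFGGSGGCRVRYHPGTRHLCFLKKNMKGWCWWAWLYQFRVKICIQ
WNSCTPHDRTCNNVQGLFHKQMQFKRHTEFICRFLWVQYRGCGADEYRNWHFQFKNNCQK
LETCFPLNMRKVQRYSFSMPPHVVCMAHVHREYRFKLEAMDWLFDIFNCAMEVQEMVCEF
EDYGNSDTWWAIHFYHPMIASIQHDWICLHCLDWAENEENMTRIVGECQCWQSYTISAPK
WPVSYKMWTWKVFR
>SYN00004_1|species_00004
LMISRACFRPFNMDFNNGKEIMQTYPYRGGYHYDQGKTWPDQFAHKQSGTSNNLPIQGHT
VMCEHVSWFHPAGYYNCLHAPTHPWFQPCWLCGSYNCISDIPYTNIVLDEWNPCPNNNKF
KWEMTNARTPDEDRNSRNDPCLWSIRRYGQTVTHHPDTACKNVLNRDMMYLRQIVTTLEC
VYTRGQWMYRRCDKFTPAMTEYEMFVEFQIPHVSGCKMVEICLAPTHRWDGGSGGNPLST
DSMYDQHAHVKKEHNLDAWIPKFTDVPWHRFHGKRSYYCREPHLENPDMSLCQVNFPHDA
WRKTPISEHCKIHTQTVPIAMGVNNYINQSYNIQFLAHGLIHAEEDENTFFIPHPVRMEY
REPEDIKQTFFTDVARKPPCDCDKWPWHMESSQDDVASNTGGSGGQVYDGWNIETREDVY
WTTERYDRTQHGWCFDHNCAWTGLGYWASWVASSVGDGCYSVVELQKYHNMVCQALPHQY
WFDVTHSACRVKRGGCVTSTTWCVIVTIAKGGSGTHQHHARYWNVLRMYTTSCFDPDQFS
QQQRKWGVGSRRSKPDAQVHRPDYDRFWSRVRDKDWDLPFLYSRDTNPMEEEKVQNETGC
FCMKDDVMQWCYRTVFAAEGYMATITGLRCTYEYVKLSTETMNLMDTRVRTWIARATSPF
WWCIMSVQWNQLNNFVFGGSGGCRVRYHPGTRHLCFLKKNHKGWCLWASLMQFRVKSCIQ
WNSCTPHSRTCNNDFLLFHYQMQFKRHTEPICEFLWVKYRGCCADEYRNWHFQVKNNCQS
LATCFPLNMRKKQRYSFSMPPHVVCMAHVHRNIRFALEAMDWLFTIFDCAMEVQEMVCEQ
EDYGNMDTWWAIHFYHSMIASIQHDWICLQCKCWAENNESMARINGECQCWQSYTQSARL
WPVSYKMWTWKHFY
>SYN00005_1|species_00005
LMISRACFRPFDMIFNNGKEIMQTYPYRGGYHYDQGKTWPDIFAHKQSGPSNNLPIQGHT
VMCEPVSWFHPAGYYNILFAPTLSWFQPCWLCGSYICISLIPYTNIVLDEDNPCPNNNKF
YWEMENAMTPTEDRNSRNDPCRWSIRRYWQTVTHHPLTACKNVLNSDMMYLCQIQTTIEC
VYTRGQWMYRRCDKFLPAMTEYESFVEFDIPHISGCKMCFICLAPYGRWDGGSGANPLST
DSMYDQHAHVKKEHNLDAWIPKFTDVPWHRFHGKRSYYCRAPHLLLPTMSLCQVNFPHDA
WRKTPISETLCQHKQTVDIAMGVVNAITQSGNLQFLAHGLIHAEEDENTFFQPSPVKMEY
RPPEDIKQTWGTDVARKPPCDCDKWPWHMEDSQDDVASNTLGSGGQVYDGWNIETIEDVY
WTTERYDRTQHGWCILHNCAWTENGYWAWWCAYSAGDGCNSVVELQKYHEWVCQALPHWY
NFDKTHSACRVLRTGCNTITTWCVIDTIASGGSGFHQYHARYWNVLRMYETSCFDPDQFS
QQQVKWGVGSRRSKPDATVHEPDYDRFWSRVRDKDQVLPYLYDRDTNFMEEEKVKNETPC
FMMKDWVMQWCYRTVPAAENYMATITKLRCTDEYVMSSTETMNLIITRVWTWIARASSPF
WWCIMSVQWNQLNGFVFGQMGGCRVRYHPGTRHLCFLKKVMKGWCWWASLMQFALKSCIQ
WNSCGPHDRTCNNVQGLFHYQMTFKRHTEFICEFLWVKYRGCGADEYRNWHFQVKNNCQQ
LATCCPLNMRKKQRVSFSMPPHVVCMAHVHRNYRFKLEAMDWPFTIADCAMEVQEDVCYQ
EDYGNSDTWWNKHFNHSMIASIQHDWICLQKLDWAENEENMARIVGECQCWQPYTISARK
PVVSPKMWTWKDFY
>SYN00006_1|species_00006
MMISRACMRPTNMIFNNGKEITQTYRYRVGYHYDQGKTWPDQFAHKQSGTSNNLPIQGHT
VMCEPVSWFHPAGYYNCLLAPTHPWFQPCWLCGSDNCISDIPYTNIVLDEANPCPNNNRF
KWEMTNVMTPDADLNSRNDPCLWPIYRQWQKVTHHPLTACKNVLNHDMMYLCQIVPTIEC
VYTRGQWMYRRCDCATPAMTEYEMFVEFTIPHISGCKMCEICLAPTDRWDGGSGGNNLST
DSMYDQHAHVCKEHNVDAWIPKFTDVPWHRFQGKRSRYCRKPHLLNPDMSRCQVNFPHDA
WSYTPISEFCKQHTQNVPIAMGVNNAINQSENLEFRAWGLIHACSDENTFFIPSPVRMEY
RPPEDIKQTFFTDVARKPPCDCDKWPWHGEDSQDDVKSNTGHSFGQVYGGWNAETIEDVY
AWTERWDRHQHGWCIDGNCAWTELGYWAWWAAYSAGDGCNSVVELQKYHMMVCQALAHDY
NFDETHSACIVKRTGCRTITPNCVIDTIAKGGSGGHQYHARYPNVLRMYETACFPPDQFC
QQQVKWGVGSRRSNPDATVHEPDYDRFWSRVRDKDQDLPWLYSRDTNPAESEKVKNETPC
FQMKDNAMQWRYRTVPAAENYMANITKLRCTYEYVVMSTETMNLMVTRVRTWIARATSPF
WWCIMSVQWNQLNGFVFGGSGGCRVRQHPGTRHLCFYKKNMKGWCWWASLMQHRVKSIIQ
WNSCTPHDRTCNNVRGLFHWQMRFKRHTEFICEFGWVKYRFCGHDEYRNWHFQVKNNCQS
LAMCFQLNMRVKQRYPFSMPPHVVCSAHVHRNYRFKLEAMDTLFTGFDCAMEVQEMVAEE
EDEGCSDAWWAIHFYESMHASIQHDWICLQCLDWCENEENMARIVGEDDHWQSYTISAPK
SPVSYKMQTWKKFE
>SYN00007_1|species_00007
LMISRACFRPFNFIFNNGKEKMQTYPYRGGYHYDQGKTWPDQFAHKQSGTSNNLPIQGHT
VMPEPVSWFHRAGYYTCHYAPTHHWFQPEWLCGSYNCISDIPYTNIVLDEWNPCPNNNKF
KWEMTNAMTDDEDRNSRNDPCLWSIRRYWQTVTVHPLTACKNVLNHDMKYLCQIVTTIEC
VYTRIQWMYRRCDKFTPAMTEYCMFVNFDIYFISGCKMCEICLAPTGRWDFGSNGNPLST
DSMYDQHEHLKKEHNLDAWIPKDTYVPWHRFSGKRSYYEEEPHLWYPDLSLCQVNFHHDA
WRKTPISEHCKQHNQTVPQAMGVNNAWNFSGNLQFLAHGLIHAIEDENTFFIPSPVRMEY
RPPEDIKQTFFTDVRRKPPCDCDKWPWHMEDSQDDVASNTMGSGGEAYDGQNIETIEDVY
WTTERYDRTQHGWCIDHNCAWTELGPWAWWAAYSVGDGCNSYVELQKYHMMVCCALPHQY
NPDKTHSACRIKRTGCVTKTTWCVIDTTAKGGSQGWQYCARYWNVLRMYETGCFDPDQFC
QQQVKWGVGSRRSKPDATVHEPDYDRFWLRVRDKDQDHPYLYSEDTNPMEECKVCNSTPQ
FCMKDNVMQWCYRTVPAAENYMHTITKLRCTYDYVKQSTECMNLMITRVRTWIARATSPF
WWCIWSVQWNQLNGFAFAGSVGCRVRYHPGTRHLCFLKKNMKEDCWGASLMQKRVKSCIV
WFSCTPHDRTGNNVQGLFHYKMLFFRMTEFICEFLWVKYRCCGADHTRNWHGQVKNNCQS
LATCFPLNMRKKQRYSFSMPPHVVCMVHVHRNYRFKLEAMDWLFTIFDCAMEVQEMVCEQ
EDYGNSDVWWAIHFYHSMITSIQHDWICLQCLDWAENQFNMARIVGECPCWQSYTISARK
WPVSYKMWTWKYFY
>SYN00008_1|species_00008
LAISRACTRQFNMIFNLGKEIMQTYPYRGGYHYDQGKTWPDQFAHKQSGTSNNLPYQGHT
VMCEPVHWFHPAGYYNCLFAPTRPWFQPCLLCGSYNCISDIPYTNIVLDEWNPCPNINKY
KWEMNNAGTPDEDRNARNDPWLWSIRRYWQTVTHHPLTACKNVLNHDMMYLCQIDTRIEC
VYNRGQWMYRRCDKFTPAMIEYEMFTEFDIPHISGCKMCEICLAPTGAWDGGSGNNPLST
DSTYYQHAHVKKEHDLLAWMPKFTDVPWHRFHGKRSYYCGEPHLLNPDGSCCQVNFPHCE
WRKFPISEHCKQHTDTVPVAMGVNHAINQSGNLQFLAHGMIHAEEFENTFFIPSPVRMEW
RIPEDIKQSFFTDVARKPPCDCDKWPWHMEDSQDDVGSNTGGSGGQVADGWNIETIEDVY
WVPERYDRTQHGWCIDRICAWTELGYWADWAAYSLGDGCNSGVELMKVHPMVCQALPHQY
NFDKTHSACRVKATGSVTITTWCVIDTVAKGGSGGHQYHARYWNVLRMYPTSCFDPDQFS
MQQVKWGVGSRRSKPDATVHSPDYDRFRSRVMDKDQDLPYLYSRDTNPMEEEKVNNGYPE
MCMKDNVMQWCYGTVPAAEGYMATITKLRCTYAYVKQDTETQNLMITRVRIWIARMTSPF
WWDIMSVQWNHLNGFVFGGSGGCRVRYHPGTRHLCFLKKNNKGWCRWASLMQFMVKSCIK
WISWIPHDRTCNNVQGLFHYQMQFKRDQEFICEFLWVKYRYCGADEQRNHHFQVKNNCQS
LATCFPLNERKKQRYSPSMPPVVVPMAHVERNYATHLEQMDWLFTIFDRLMEVQEMVCEQ
EDYGFSDTWWAIHFYHSMIKSIQHDWICLQCLLWAENEENMARIVGECQCWQSLTISARK
WPFSYKMWTWKVFY
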