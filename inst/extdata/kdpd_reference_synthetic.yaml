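id: KdpD_reference_synthetic
sequence: LMISRACFRPFNMIFNNGKEIMQTYPYRGGYHYDQGKTWPDQFAHKQSGTSNNLPIQGHTVMCEPVSWFHPAGYYNCLFAPTHPWFQPCWLCGSYNCISDIPYTNIVLDEWNPCPNNNKFKWEMTNAMTPDEDRNSRNDPCLWSIRRYWQTVTHHPLTACKNVLNHDMMYLCQIVTTIECVYTRGQWMYRRCDKFTPAMTEYEMFVEFDIPHISGCKMCEICLAPTGRWDNPLSTDSMYDQHAHVKKEHNLDAWIPKFTDVPWHRFHGKRSYYCREPHLLNPDMSLCQVNFPHDAWRKTPISEHCKQHTQTVPIAMGVNNAINQSGNLQFLAHGLIHAEEDENTFFIPSPVRMEYRPPEDIKQTFFTDVARKPPCDCDKWPWHMEDSQDDVASNTQVYDGWNIETIEDVYWTTERYDRTQHGWCIDHNCAWTELGYWAWWAAYSAGDGCNSVVELQKYHMMVCQALPHQYNFDKTHSACRVKRTGCVTITTWCVIDTIAKHQYHARYWNVLRMYETSCFDPDQFSQQQVKWGVGSRRSKPDATVHEPDYDRFWSRVRDKDQDLPYLYSRDTNPMEEEKVKNETPCFCMKDNVMQWCYRTVPAAENYMATITKLRCTYEYVKQSTETMNLMITRVRTWIARATSPFWWCIMSVQWNQLNGFVFCRVRYHPGTRHLCFLKKNMKGWCWWASLMQFRVKSCIQWNSCTPHDRTCNNVQGLFHYQMQFKRHTEFICEFLWVKYRGCGADEYRNWHFQVKNNCQSLATCFPLNMRKKQRYSFSMPPHVVCMAHVHRNYRFKLEAMDWLFTIFDCAMEVQEMVCEQEDYGNSDTWWAIHFYHSMIASIQHDWICLQCLDWAENEENMARIVGECQCWQSYTISARKWPVSYKMWTWKVFY
domains:
  KdpD:
  - 1
  - 230
  Usp:
  - 231
  - 395
  TM:
  - 396
  - 500
  GAF:
  - 501
  - 662
  DHpCA:
  - 663
  - 894
anchors:
  walkerA_G: 36
  walkerA_K: 37
  walkerA_T: 38
  adenine_W: 39
  walkerB_D: 109
  walkerB_E: 110
  adenine_R: 190
  HK_His: 673
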