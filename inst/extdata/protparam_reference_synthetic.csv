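accession,sequence,mw,pi,gravy,instability
UBIQ_HUMAN,MQIFVKTLTGKTITLEVEPSDTIENVKAKIQDKEGIPPDQQRLIFAGKQLEDGRTLSDYNIQKESTLHLVLRLRGG,8564.7357,6.5616,-0.489474,36.0553
SYNPP01,LNQLRYKCDKDYEDQKCQQAKRQRGMENQDNGITTDRKLMLRHELDTMPCNNKAWDMSSEDDAENNDVVQRDMIVMKWQDQEDRQEGGSDCQNESEQVNKGQDLYLHNSEERKDKICNKRRRPELECSQQAKFELNDNEWQYCNFMPNGQKWNWENRFHNRNDQDDDSRQNTCNRQNKITRQHGKVRERISDLLYKNDEYDKGLKNQDKQDQLNNDCTWKEPHPERKSCERCKKKNNFEKYNKNEQENHRDRKTKQDNLQKIDFVEDYEASMRWQKKERSDCENVIRPIRYNNGRE,36135.2018,6.1901,-1.870608,50.8834
SYNPP02,QETWETKNPNMAYIWWYIYQERTSYSSDNGVQDTGPGFEQWCDLFLAYRWDWGKKMETIGGKFIGRMEEEPSCIYHLSWSRGNMYTWWGGHRQWPAEADSGAQNTWSTNGLDANSPFKRIWQITQAMLLNQFPGYAHVGNEAQGRAAYTRHVFCMTGHYAMWCYQHHENPGVQTNPLTYVLTEQGRFHQGKFMDWSITDGGFTSNCVCALQTTLIEKKPYGWGVENNHGCRDNDAKTEWSVLCDYVRPCAANRYFPDTWVKMKYYYMIEAQHYYTRRYMCNDWCDKVMVSAQECHLPDEGHAPVQMMYFDPVSNGKPYASAFLVQHLIKYGVIIGWDYMWMMKHAIQCLHC,41240.0899,6.2,-0.597436,39.8707
SYNPP03,RLVLLKTIEVVLKNFFLILLYEWKTNSMTKVFMQKWFFVVVAWIGILFFKSIILLWVLEHIWFVLSFVIDAIFFAQFCYTLINCWEPLMQGPFANGARYCLIVYTSEIEIVMPVDFFKCIWGKQGINVYNVYSGFIINIFRIFGEAQCWGILQFDYNNKWINDWWGLMVNHHYIIDDASLVIQFFLDMQILFYMSKFFESLRMEVHSPLPWILNIWMFENSNFYTEIMVSEDMYFMDWIWAFQASVGPSGQILTGQFENNCKSFIRFRQFYVPFIKEKIENIVFQASQFMSLGEDQYVSLMQLCVYVLGIQDYVHYNHICQLQSLFEEHRYADHSIVAVRIH,41052.674,5.4556,0.435965,41.8796
SYNPP04,RNQQATQEKRNDFIVFMFGAWKCMGNQYHDKQYAHPWDNGQRKNHGTNTHKNMMSDSLRELIECQLRNQEPKAQMINDQRRITDRKKQWNRERGYRKQDAFLDKKWQEVNQKVYDDRMIGRSDQARTRERRWDEMDQDQEPQREYCRSQKKENIQEQSERRDQKIVQNACQERDKKEPFEMNQQYANEYQFINESPEDHWPRMWDRVDTKMEFHFNDQDDKDYDNFWLLQIYVMGGRKHFAEIHNEPTHSEPNGCEPQNATNDHDLDNQIRAWDKNRAEENKIEPKEMDQRLWERMDVEDRKYASWQHNNPNPQDNPQMDIQRKAKNHQGKKER,41122.7451,6.3575,-1.794012,53.456
SYNPP05,TQTAWIAFQEEVKQRHACYSHEVGEHFHTGKLDLDHWIMMIEHGQMFFAAETQHVNPLFFLEEEHSAIQFTLNFWSNYHKGYLYFDVLNFWIRWWVHTLGKNEGPVDRMVCIRLFNFWLVWFFFHTRHCGLTQNCSAPWTMSQTMHRAVTWMAVWMYQNGLKMPACNFMDFPYPMIFIFWIVKHTDDLAPTGTDHHKCWHNLEENGVTHVK,25460.9065,6.2795,-0.22654,35.2782
SYNPP06,PVVVVIVWITSDIHNPKPVLPYSKWAVILQSMQNSVLNGIYELGPITSKSCWQVMFSVASCVSTRQCIKCLIFQRLVIQTSTFLIANALMLLDFLFLIGRTCSLFVNILLIVVQLVKFHLLQVRMMQVFLVWLSPIFLGRFAVIKGQSCIIMNWLKGHGK,18167.9383,9.794,0.8975,32.3781
SYNPP07,QQEVNRTQDQTDEAMTENQHDENMANAYRRPQDVYERQWRKRRKIRREGNKMDNRYSPGTPGPCHRGNHKNDYKNCPTRYNRMQEWEVQAWEQRESNRRHVRMSTYIENMWDRKMRQVNLMDTRKGRKTKNDHSCRLVADNSLEEGHQYENAQAWNQQYEYLKKEPAQPIPELDLKQDR,21968.9969,9.236,-1.856983,53.2592
SYNPP08,TRTQMIGTTIFCKSYVPHEMNMHHVSVGSERNFSRYFNELNSASCSVGRQPTHQFFTCETMREEFFDFGNMYFNQCDQWDWNFIENTLPHFDCEDPVYRDRGNMKDPMKWFFQDDHHKKSYLGMLEMKHTCHFYRFPNY,16976.8613,6.0987,-0.84964,32.4612
SYNPP09,ALLGQLVQLIWTDLLVVVSYILNFIVQLTLLVRIVLIWVVYFASNPSDDMKHEIDILQQPKCPPIFPIMLFNMAEPSVIRCQSEYRICIPKINEGYGMTLLAVFAEQCVKVACVTQAIQRVHICIIVRKCHIFFIFRFPHLCNRIGFLLVSLTNRVFVPVNLPYKIERNSVFGVSVYVRAEKFFISIFREQDHHLKCVFLDTMVKLFIDIKIHDCAECVV,25505.3787,8.4991,0.683636,30.575
SYNPP10,LLSWDDDNDEQSIANTDGMRQDVYNVERMRNMDRRQKNRGHQAQHEERYMNEYKLNRQEDEKKVNIDWKRERFPKHFEWNERQNNIRNGRDGNRCGINDAVLFRKINNTDQCREKKHKPPVWDGKKREDWYEVDQSNNRRTDNRDKARDIGQKFEPNCYRERRHYQDNWWRDRQAHREWQEIREIWQNQTVDVHQEQDDLKERTEAKVHKDNTNQDPERNTEFSRDTKMEREGFIKCDDNQHLNRVFND,31004.3477,6.5691,-1.950201,43.2104
SYNPP11,QHPLQSKLDHQGECMACNANECHNQDLLRRRAKKVNPQSCWMRLEDKQQCPKLLDLFSIIMHEMNHMVFTKKYIKCIRLWCPGERQETWHASWRICCHLLSRVRSLHKEEMEQGTDFHHRQHTNQRTCADPCINMHMQRFMSKWDMFMHLWGDRCLLVYLPFVMISTGVKQYTNYTRMYPNSGDAIFGMCNYVMRAWPYIGLWLLCFNMFLAQPLGIQGLCRSQGDECCANVVVAIRRYRFRWFVAWNNQNVPPNFGHIMQSIEQPHADYSDRK,32741.7556,8.8976,-0.473358,64.8693
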