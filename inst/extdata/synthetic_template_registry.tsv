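pdb_id	kingdom	product_class	f1_s1	f1_s2	f1_s3	f2_s1	f2_s2	f2_s3	f3_s1	f3_s2	f3_s3	sequence
2FOR	Bacteria	C15	148	182	216	152	186	220	156	190	224	HFKLNHMNRVTFKAMSSIMCFGGVIEIIGGTKNEVIVRHMAFAWPNTVRHDCFRWPHNLHIEVMGVIDDYHKMWEPGQYKNDKNKCPCLNTVDCWVNEPYSWQAELVYMGKICFHWMHFEACLSQHKGYAFCFTHPTNKCVFDFYRILQGAGYMSTRPSIKMNWQFPEMMAKPCAAVHKQEYSLRTKEGSWSQCFGKKWFTNLAWENKASPFIQILFHLAFVGAMTGTERTNHDNALYYKYDHCHPLGCFATQSRIVHDHEASKEPWVIIEMKINKLPKAVPVDWNYPKCTGHRVYRTPGHAGVHWDPFSMKGYVHFLEW
3OYR	Bacteria	C20	148	182	216	152	186	220	156	190	224	HFTNNHNAYVYTKAMDSILVFGGVQEIINCTKNWHIVRAMSTCWPPTKRHIISRWPGSCHILVTNVIDDDQKDGEFAQYFKDKNKKPCLCEVDHFDQEPYSWRAFLVYMAYCCVHQMEKEACSSLDKLVAPYGCYYMNKCYFDFYRICQLAWYMSAYCVGKSSWQLHGMIVKPCAAVIKQMASTRMCEPSHMTCTGMKWFTALDDETKLLPFQKIAAHLWFYGGMPGHEFLNHDNAMYLKSPIEHVRAPFCGQSHITHDHEAESLSWQLICMKINKLPMERLICAFLPACTKQRHQRAPLHSGVLVPMFMMKWKPHFLEW
3QQV	Bacteria	>=C30	148	182	216	152	186	220	156	190	224	HFTNNHNNWVTFKAKQETGVFFHVQPIIHFTKNHKIRWAMSFKWQWDKVHICFRNPCALYHEDTWVIDGPHLMWECPQPFSDKNKAPCLPWVYHMLNEDYSWQRFLVGMGTCCVHGMSSECCLSFNKEVATCFHHYHIKKVFDHYRITQLAAGRSGPHKIKSAMQYPGMMRHPVAAVIKQDGSTWCKESGASGWFFGKRFTALDGENLAPCFHKDCHLLTFVYGMPGHEFDWHDGAPYYPYDWEHVRGPFGGPFHHVHVQAAEALIWQIICMKINKLPRSMLWCWEKPKATKQDLYRTCLHMGVEEEMFMGKWKTHVYEW
3PKO	Bacteria	>=C30	148	182	216	152	186	220	156	190	224	RFTNWHENRTRFKAMQSILEFGGVQYDIHCCKNHKLVRAMSFKWPWTKCHTCFRWDCNLSSATVNWIDAYFKGWELTQYFSDLNKKPWLLVVYYMLNENYSWQATHRRMGTCCSFGMEREACLSLMKGVATWFHHYHIRCLFDSYMSGQLACPMSCRPVIKSAWQQRGMWYKPCAPEIKQHGSTRCKEQGFSTCPNGKWFFLLIDENGAHPIHAICFTASSNTAMPFHEFVLLDDAPHIRYCWEHFGFKMGMQSHIVHDHEAERVPWQIICMKINHKPPSMLIPLFDPKYYRHTGWRRCLHCGVHSMMFAMFWKDHFCTP
1WMW	Bacteria	C20	148	182	216	152	186	220	156	190	224	HYWNGVNPRVTRKDMQDDLVFGGVQEIFNCTKNMNILRAMDFKIPWEKRHMTFRWPCQLHRERTGFMDDTHKMCECMQYLSDKNCLPQLPSVDHMLIEPYSDQAALVYWGACCVRGREFEAFLSRTMLVATCMNHYIIKCVFDFYRIGQLAMYMSTISVIYSAHQLPEMQAKFCAATWKFICSTRWKAQAHSQFFCGKWFTALDDFNLAWPFVQIASHLYFVGTFPCHEFDIHDNASAYKCDWEHVRGPFGGSSHIVGEHEKECLVWQIIPMKDNNLPFSMLICVFYRKCTWQSTYRTCIHMGYHKPMFHMKGKPHF
3Q2Q	Bacteria	C20	151	185	219	155	189	223	159	193	227	HFLNYPNDRVTFYAMQSEQVFHIVQYIIPATKNHSKVRAMGFKWFGTKGHKAFGWACNLHVMFNEVVVVIDCHQIMYESAQYGLDKLKKVGLPWVIHMSLEPTSWQASAVYFGTCCVHMCSKAMHCSLTRLVATGFHHFHDECVFDFCRISQLQLYMSASPIIKSYMQRPNMMAKDHAHVHKQCTSTRMKEQSNHMCAGGKWRKARDDRVLWDPPHQISDHLWTVGCMPVPEFDNHPNAPYEKYDKYHVRFPDKSTSHIHHEHSAESLPWFWIPCKINKLLMSMLICQFYGKCTKADVYSTCLQMGVHMPIMMMSWKSHMIEW
5E8H	Eukarya	C20	148	182	216	152	186	220	156	190	224	HFTNNHNGRVTFKAKQQILVFGGVQEIIHCTKNHNNVRAMPFKYPWTKRQCCNRWPVNLHIEVTGVIDDYHKMWECGQYFSRKNKFPCLPVVDFMLNEPYSWQGFLVYMGTCCVHGMEKEACLSLCKRVATCFCHYHIKCVRDFNKIAQLALYMSARPVIGVAWQKPGMMQKPCAAVILQHCSHGFKEQTHSECFPNKWFTALDDSNLAPPFHQITFHKMFVGAMIQHVFFNHDNATYYAYDWEHVRGPGGGDSHIVHAHENESLPWQIICMKQNKLPFSMLICSSYPKYTKQDVYRTALHMGVHWHMFMMMWKPHFLEW
2E8W	Eukarya	C20	152	186	220	156	190	224	160	194	228	HFTNNHLNRRDFKAMQSIGKKGSVREIIHCVKNHNIGRAMIFKCPWTKGHIFFRWYCNLHDIFVIEVTGHDDDYHTMWECAQMFGDKSKKLCLPWVDHMLNEPWSWSAFLVYMHTCRVHGMEFEACWSTFHCVAWWFCHYHIEGSFDFYIIAQLCWQMSTRPVIKSAWALPGMNAKPCAAVYKCHAHTRFKEQTHQQCFGGKDFTALDDEGSAPPFHFITFHLLFVGSMPGHEFMNHDNANYYKYDWEIVRGPVGGQSEIVHDHEAESMPWQIICMKINKLFFFMLHCWFYPKCTKQDVYRTCSGQGIHWVMFMKYNKQHFLEW
1FPS	Eukarya	C15	148	182	216	152	186	220	156	190	224	HFTSNHNIRVMRFAMQSILSFGGWQEICHCIKNHNIVRGMCFKWPYTKRHERFRWPCNLHITVTGFIDDYHKSWECGQYFSDKNSKPCLMFVDHMLNEPFETQAHVVYMITCSVHGRETEALLMLCKLVATVFCHYHIKCVFDFDRIWQLATYPAARPVIMSAWQLPGMMRKECAGVIKQHWSTRCKEQTLSNTFGGKWQTALDDELMWPPFHQIWFHWCFVGTMFGHCFLNLDNAPYYKEDWEHVDGPHEGMNGIHHDHEKESWRMCIICMHINKLPFSMLIDWFYPKCYKQDVERTCLHMAVHWPMFMMKWKPI
3AQ0	Eukarya	>=C30	148	182	216	152	186	220	156	190	224	FFTNNHANRVTFGAMQSILVFGGVQEIIHCTKNHNIPRAMSSKLQWTKRHICFFWPHNEHIEVTGVIDDYHKMWECHRFFWDKNKKPCLPWVDMELFEPYSWQAFLVYMGTRCVHGMEFEACLILCKLVATCICHQHIKCVFDFYRITQLCAYMSSNPVIKSARWSPGMMASPCAALIKQHGSTRTKEQGHSQCRNGKWYTALDDENKAPPKHQIAFHLSFVGASPGHEKMNEDNAAYYKYDWEHVRSPFGGQSHIVHDHSAESHPWMIICMKINKLPRSPLICWFYPKCTKCVKYRTCLHMGVHWPMFNMKWKPHFLEW
1WY0	Archaea	C25	154	188	222	158	192	226	162	196	230	FFRSTWPNRVTGAAMTWYRVFIGVQEVIGCPWLWNAVRPISFNINITGRHICYRWCFEHHMGLTMDISQHTVIKPYCWMWVCIPQFWDKNKEHCLPWTDMMDNIPYSWQTFPSYKDPCCCSGAHLNDCFSSHKNVPTPFCHYHIKCNFDPMRIGQLACYMSMTDVITLAWSWPPMMAKWCAPVIKNHSEIRCKENLGSDCFGRKDWEALADENLFPPFWQRTFNLAFGGMMPTHTFDNHVNAKSYKYLWEVSRQPCGNQSHIQLDHERESLGYQEICLKINKGPFYLLICPFMPICHHQFVRRFCLHMGVHLLRRMFKPKPYVLAK
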