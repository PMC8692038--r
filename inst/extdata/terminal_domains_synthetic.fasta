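>MaSp1_NTD
MFKRRMRLPARRMSLESSVMKMKCPNTSPQHWTHTSQDELEWHWVKVPRYMNKYMAPPVY
ERNKVWWPFNPKMQKQVEIAQEYLMNGTVNFMVPRVQAENYNYYKPKMRRKTNLQQSSIT
RWRGLTPPYMFPLGVLVEICRARDVQGSKQ
>MaSp2_NTD
MFQPIMTKSNEGCSIMQSSRHDKCAKLSVTLRTITPEDTMPVCRVKKKHYKCKIMSHDHI
LNLIHWEHNPPGQQGRTMNARTYIDHFNRNFVVPRSQTRLEQGPHKKHRWEYGVHTSESD
PVMTLTRPYMRHVMHLNEQAGANQVLPLQD
>MaSp4_NTD
MFQPIMACSQEGCSIKPLSRHDKGAKLSMTLRTHTPEEGMPVCRVKKKASKCKMMSHDSI
LNLIHWEHLPPGIQGKTMTERTYDDHNNRNFVHPRSQTRLELGPNKKHRWEYNVHTSESD
HVMTLTRPYMRHVYHLNEQCGANQVLPLQD
>MaSp3_NTD
MQSDRMGCSNSREYFNKKDSKREIMDKHMLDCTYVPQFKIMVIYVKSGMYGEKRGKVPSH
CQNKYWCHLCPQMQDVVRNGWTYDMHGHVNFRISYSQARYTVYCWWKLAWHPCVHFSDMR
GVMGLTVYTMHGLIVSRENTKNRQRQLKKH
>MaSp5_NTD
MFKFKFRCWNVKCYHQSKSMNIKMWSASQTVITIELENGMRVHKVAPWRFGWMCLPHHYF
CLNKVWLAKVPIPQHPMVYAWTYTLAGTVQNDVDRSQVRGLVLCREIMRWKENVHMWKLC
GMYQDAHAYMHPEMHQCEQCDARHVLVSKH
>MiSp1B_NTD
MFGQIMNATNLACSKLGMSFVRKLWEGSVTDSQHADLDGIPQSRVLMHRNGNKIMKHIYI
YCWKSWLHLYPNSQYQGSIARTYFMHGTDNERVPRVKQFMICGMREADLWQYEVYTISTA
TEMFAIVSYMMPLWHLQEMCIAMQVQPLHF
>MiSp1C_NTD
MFGQIMNATNGACSKLTKSFKRWLWEGSQTDSQHRDQDGNPQDRVSMRRCGNKIMKYIYI
YCNTVWLHLYPNMQYQGSIAVTMFTHGTDTERVPRSKQFMDCIMREADSWNYEADTSGTA
TEMFAIVSYMMPLGHLSEACIANQVQPLHF
>MiSp1D_NTD
MFSQIMSATNGACSKLGKSFKRKLWEGSQTTSHHRDQDGIPQSRVSMHRCGNKIMKHIYI
FCNKLWLHSYPNMQDQGSIHVTYFMHGTDTERVVPSKQFMDCIMREADLWSKEVDTSSTA
TEMFAIVSYMMPLWHLSEACIANQVQPLHF
>Flag_NTD
MFGDIVFEENKFCSKNSNSMMCTWLKKSMSVFTSACQMFIAVSWDKKPVLTDMDMKHNVI
SLNKVWIHNYIGIIHPMMIDHTLDDCGIMNTTCPRMFVYHRIWYRCFTWWKRNVHTVNTD
GVMGLRVPYTAPGMNTNEWCIARHDQSLDH
>MaSp1_CTD
MWSLYWEKAPWKVTWVWQCEWRENSSISDNEPVLKPIMGYGWFGTCWFCDDIFWSCCIIF
SGCVTQAMAIEHQSWWNSYQLNHCQPHTFIREKRFYCPKM
>MaSp2_CTD
SRCDFPKIAEMLTHWMRKICHEENSGIRHCDCANSRLNHGWSFGDCWASPMDNDICPIIF
QIAMRQGYFIVHECHACIANHCVNHGPWMTLHCRPVCPKI
>MaSp4_CTD
MRCDFPKIAAMLTHWYRKICHDENSGIRHCDCVNSRLNGGWSFGKCWASPMDNDHCPILF
QIAMDQGQFIVHECHACIANHCTNTGPWMTLHFRPVCPKT
>MaSp3_CTD
MRQIYMCILEIQTVWWRYIEWTDASTYTWNEEYNSPINVLVDRGFCGPSETIWHYCHKIF
QGCMYNGYAIVHIYKHNQCCYNVIVFSWGFCMHMWDVKYA
>MaSp5_CTD
HRQNYGFEAKRCTQWFHDAEATEHSYHHDEILVEGCKMYGLDSGHRWASLLLLTVCNIYT
FDLVKMGYAQVHQCKWKQPCNQYKTYRCWIRLLRFPMPKH
>MiSp1B_CTD
MENAYWEYAGRGTQWKRFIEATIMRSIPAKLNIEGPIHYCFEFGTPWAVLVIGDSECIIF
QIFVRQRPPIVHDCWWNYPCYCHHEYHAAIDCNRFPMPKQ
>MiSp1C_CTD
MVNDYWEYACRGRQWKRFIEATIMRSIMANLEIEGPIHGCFSFGTEWDVLVIGDSECIIF
QIFVRQRCPIRHDCWWNRPCYCHHHYHAAIRCNRFPMPKQ
>MiSp1D_CTD
MQNAYWEYAGRGTQWTRFDEATIMRSIMANLWIEGPIHMCFSFGTLWAVLVIGDSECIQF
QIFVRQRPPIVHDCWWNYPCYRHHEYCAAISCHRFPLPKQ
>Flag_CTD
ARQSYSEPAEQQTQEMEDREASFNVSPWVNYYVFSTSNGCWDLGTEWDDLKKQDSCCIIS
QAMPKQGRAVVWFERWNYPKYCCYKFHWHMREFEFDMPNC
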