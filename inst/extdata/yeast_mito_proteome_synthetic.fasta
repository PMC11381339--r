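>COX1
MIFLFLLANAILGPVQMLITAPILSVLFILGAIYIVPHTIYIYLIYVTYFAGGENSTTIAMGMKSITVRY
SSGHWIVRVLDAILLAMTEILLLNTSIGGIISTFPRGANFKYNIVETFSGIYFWLNLLLYGLQTGWVMFK
LKTILLRLNTYTTLAAYSTLIMIGVAVIGNHIVFCPPSIVILCYKFVGHISSLYILKLSSGIYSILFSLV
GQELFSFVLNINLNSMSFANYGNVISPMLTLALTKAGGLMIRWFCILVLYALLVVITTFKVLYISRIFNL
FSHQTFAGIVNNELGRIMYALPIVFFLFVVASYENFLLRFSLGSVDDIGGNRFVPYAYNIWATRYISMAL
FFAISGILFRLGTYTITNIINPLYYCNFILLASFSLRKASTGYPSFEVEFQFSFNRCIVAPINRFENKML
IIHFYLKLYLLNDGFTYASMLEYYYPMFVIFLSNMGSEYAWGTKIVFFGLFGFQNDTSNISNPMWKFGLG
LFVVTIGLAILCYKLYTMLLVSWSSFGLFMHTSVLGTWAPFKYW
>COX2
MARNIGSMIMIGRYIISNEVTIWHAHFTNLHKGLPYNYMNIASSYNGHNPQKYIIIYIAAYFLMFSGMPF
YAHAIALQIYVGFITNINFFFVIATVIISTEVGNFSIIIFWNTAILGSLFFVSCIFYIIFNTYEPSLSFG
GSFPFNCILSELFIGFSYFLTITITSFTFLLNFFAEFMITSGVKITFGSIHPLINLCGFSTYRNNTNNSN
KLSIIVLFWPQLLTANMFLQHFTGATVPFSFLSLYVTFTLY
>COX3
MYTGFILMQSIPDLIVTSWGYVAALMHGLAFGVIALIFFVTTMMMIVKFYTYSFKMDFPRKMFSVLFECN
QSANLAQIYKLLIDPKFPPTMKNGLLTSPLTYCRMALIVIINAINNNVLPLTIFYSSLPYFARKVYSSQL
LAMNIHMNAHFWEVPFAINTSKFLIILIFAPFFKERLSFKYGENMFLGILEFKIILFFYISSIVSQPAFF
FAVFGLYTIFLSCILKMINNDGKYLILYFDSAFQEVIFNLEITAIKIIISLDFIFLLWL
>COB
MYYGFLMVPAGLGYMVSFSFVNFLFTGLLSFLYQHDATGSIFVPVFIANNHSIVWYVIGNEGMTNGFFFH
NKPYTLLFVGLSNKAMEVAITSFLLKYGYIFVLATVTISSMYYFYYNILAGIIIFSLVYNKMLLWWVFTM
PISGIFKIVLNLVHLGFIGTSGLDRNITANEKNQFSQHVSLGAFYIMNITYLTIILPAAAVCMELNIGAL
HWLLALRHWFNAVVNQFNLVMLNPGKIVIPKVTFAIISGDWTTISTILFGLRNNTILTLSWAMGDGKGSL
YIGKGRFLLSIKCANYITYTFFTSNNLIITTITLPNVIGYGILNSSCWLTQLVPNYWFFSTTYKFVYITS
IVFGGIARVTEQLSSITFQTAPVLAWLYNSFTAGT
>ATP6
MNFYSGLFLIGVFVMLLLLGFMRPIVILAFMMLLLVNGIFIILNIGSFFINVFDITFGEAANFGPIFTNS
TITGMIFSIIASMLLSVYINITYLGSYMGKEPSVVFNNYNLGRRYTISPAKTEPSLNLTGAKIAGSAMYT
IFLSGYHGYNNKTLTLALVTFVLFGQTSQTLYMIGAFSKVLLISLPTTVILEYKLDLGLNFTTRLKGNLS
TALILSITFLYISNQPYVFLPTVLYGIVVILIHVSSQQYICMWTYFINI
>ATP8
MTLVVYYWGGLNSVIFDALSFPYLVSWKLIFGSYIALQYQRIGLPSQH
>ATP9
MIWIAVLQLGIIVTILLYSWAFHSIFAIMYIKLLAHKSSNIYAAAMMRELILWLMLGNEVSLALAYCVFI
VYPIMM
>VAR1
MFYEDCGKAVYNINNNGNGKYEKYNRLTSLASNNTGQKSFHIYIFIHCNVSSYNILSYKNDNYLGIAVAS
AINTYPSELLNMNSLVVLNNLNKYANIITKIATTLSRLKINFMMAIILYYVTLIKSKTSRFSGQFKLIFG
LKYNRPGLDPNGYPRNFIEPYYNSFYKYNYIPAYNKQDAYFKSNFFNMTISLKHEDDAQCYESKNLSYKI
RYLSSMQKRPKSTSHWKIYYAHNYNLEIETTYTIYTRAFLKQNYCLLNNSRIIHGMNTKQNNLFNSLSYN
ENLVIYSAVFDLLIGMAMSYKQNYLKLNYWDSNVELRKFKITTPSPLVNSIFLQQNHGAEKYYFEKMSSL
FKRKPMLKMKNILSYNSGRVKTNGKNYKFSCKNLIGILTRTNSGTLKY
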