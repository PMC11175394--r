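THABO
SIPHO
BONGANI
THEMBA
MANDLA
SIBUSISO
NKOSINATHI
LUNGILE
NOMSA
THANDIWE
ZANELE
NOSIPHO
BUSISIWE
NTOMBI
LINDIWE
PRECIOUS
LERATO
KAGISO
TSHEPO
KATLEGO
PALESA
DIKELEDI
MPHO
NEO
REFILWE
BOITUMELO
KGOMOTSO
ITUMELENG
ONTLAMETSE
TEBOGO
KARABO
LESEDI
SIYABONGA
VUSI
XOLANI
SANDILE
MUSA
NHLANHLA
SAMKELO
AYANDA
ANDILE
WANDILE
ZODWA
NONHLANHLA
GUGU
DUDUZILE
PHUMZILE
KHANYISILE
JOHANNES
PETRUS
HENDRIK
WILLEM
JACOBUS
FRANCOIS
PIETER
GERT
ANNA
MARIA
ELIZABETH
SUSANNA
HESTER
MAGRIETA
CATHARINA
JOHANNA
JOHN
DAVID
MICHAEL
PETER
JAMES
ROBERT
WILLIAM
GEORGE
MARY
SARAH
GRACE
FAITH
HOPE
JOYCE
AGNES
BEAUTY
RAJESH
SURESH
ANIL
PRAVIN
DEVAN
KUMARAN
VISHNU
MOHAMED
FATIMA
AYESHA
ZAINAB
PRIYA
KAVITHA
DEVI
SHANTI
ASHA
NTOMBIZODWA
SIBONGILE
NOKUTHULA
THULISILE
ZINHLE
NOMVULA
PHINDILE
SINDISIWE
MXOLISI
SIFISO
MDUDUZI
SAKHILE
MELUSI
BHEKI
JABULANI
SENZO
PULE
THABANG
MODISE
KABELO
OFENTSE
GOITSEMANG
MMABATHO
SEGOMOTSO
CHRISTIAAN
STEPHANUS
ABRAHAM
IZAK
BAREND
MARTHINUS
COENRAAD
LODEWYK
ANNELIE
MARIKE
ELSABE
RONEL
ANNETJIE
WILHELMINA
ALETTA
MARTHA
JOSEPH
DANIEL
SAMUEL
EMMANUEL
ISRAEL
SOLOMON
GIDEON
ELIAS
RUTH
ESTHER
NAOMI
REBECCA
MIRIAM
DEBORAH
HANNAH
LYDIA
KHOLEKA
NOMBULELO
NOLUTHANDO
ZUKISWA
BULELWA
NOMAWETHU
VUYOKAZI
NTOMBEKHAYA
LWAZI
AKHONA
ANATHI
SINETHEMBA
SIPHOSETHU
LUKHANYO
MASIXOLE
MONWABISI
TSHEPONA
MAMENDO
MALAYO
LUBALA
SIWELE
KHAKGOSO
MPOMENA
MONYATU
TSHEDULA
ZATHEYO
MPOLAZWE
VUHLAMU
MONGAMBI
NOWEPE
KUTHELE
MOMIZWE
ZATSOKA
ZADUTU
VUTHENI
LUZIDI
SINDITHI
NTAREKA
NONYALA
LEPOMBI
KULAPE
NOMIZWE
SEZINI
DIPOTHI
SEMEMBI
LEMENI
NOREZWE
TSHENYATSE
LEMINI
MOFUKA
PHUMINA
MALATSE
KUNGASO
LUPOSWA
DITSONA
NONYAPE
THASHANDO
GAMEKA
SENDIZWE
ZAZISO
MPOPOKA
MAHLAWA
KHAWESWA
NTASHAPE
TSHENYATU
MAMETSE
NOLAYO
BOTSONDO
LUFUWA
MPOMINI
KUKHUWA
THAMILE
VUKGOLA
TSHEFULA
GAWEBE
LELAYO
VUHLALE
PHULAKO
GAFUMBI
THAWETU
THANGATHI
KUBASWA
NKALAPE
MAFUSWA
SESHALA
THADUKA
MPOREMU
GAMEBE
NKANGATHI
LETSOTSE
NKALOKA
MPOBANI
GALAKO
BOKGOMBI
SEMETSE
KUNDITHI
LUNYAKO
MOTHEPE
LEREBE
SINGAKO
KUNYAWA
GADUBE
ZANYATSE
ZABANA
VUNGABE
LERENA
TSHEZIKA
NKANDITU
SIWETHI
MOTSONA
SETSONDO
MOWENI
KHAFUSO
BOPOSWA
DIBAKO
GAKHUDI
DIMENA
SITHEWA
PHULOSWA
KHAKGOMU
SEWEDI
MPOTSONA
NKAMITU
KUTSOSO
VULOBE
NKATHEPE
THANYASO
LUTHETSE
MAHLALE
ZAPOMU
SIKHULA
SENGAPE
DINDINA
MAZISO
MADUWA
SIRENI
ZAMITHI
PHUNYATU
MPOKHUMBI
MPOLOLA
NODUMU
PHULAPE
MOBANA
MAMEBE
PHUNYATSE
THAFUMU
NTALOSO
BOTHETHI
NOPOKA
MATHENA
NKANGAZWE
ZALOTSE
KULALA
VULODI
SEKHUNDO
VUWEPE
MOFUSWA
SENGANI
NKAPOMBI
LEBALA
MAREBE
MPOTHENA
KHAREMBI
SEWEPE
NTATHENI
MAKGOSWA
NTAPOSO
DITHENDO
LUWETSE
KUKGODI
GATHENI
MAMINDO
NKATHESO
PHUZIZWE
BOBAKA
GASHABE
SIMIMBI
VUHLANI
DISHATU
SITSOLA
TSHEFUKA
MOMESWA
KHAMILA
MOSHAMU
THAHLAPE
NKADUKO
VUMIKA
LUWEKA
SINYAYO
MATSOPE
LEMETSE
LUNYADI
VUHLALA
MAZINI
MABAKO
NKADUPE
THALANI
KUKHUTU
MPOLALA
NKAKGOTHI
LEZITHI
MPODUKA
NTAPOMU
MAWEBE
NTAMETU
NTANYATHI
BOLOKO
LUKGOYO
ZAFUDI
VULOSO
SIREWA
GAWETHI
LETSOZWE
GAKGONDO
DIDUMBI
VUBAMBI
PHUDUPE
NOMETSE
NKAZILE
MAKGOTSE
PHUWEKO
LUFULA
ZAZISWA
KHAKHUPE
GAWENI
MATHEKO
VUKHUSWA
KHAPOTSE
NTARESWA
ZATHESWA
BOTSOTU
SEPOBE
MPOKHUSWA
NOTHESWA
ZAHLAPE
SIMILE
DIWESWA
SITSOYO
PHUTSOMU
PHUWETHI
MPOZIMU
NKAKHUNDO
GADUTHI
NTAMINA
LULASWA
NONDIDI
SETSOTU
KHAPOYO
SILOPE
THALAYO
SIMENI
TSHEZIWA
MPODUMU
GALOLA
LEFUNDO
SIZIWA
ZAKHUKA
VUTSOWA
MAPONDO
NTAZIZWE
DISHAPE
LUFUSWA
THATHESO
KHAFUMU
GAMEMU
NORENDO
KUSHAKO
LEWEPE
NOMENI
MPORELE
MAKHUTSE
MPOWESO
SEBAZWE
KUHLATSE
LENGANDO
VURETU
PHUHLAMBI
LUREKA
LUKHUZWE
GANGATU
ZAREWA
KHAREWA
NOTSOTU
ZANDIDI
NTANYAYO
SITHEMU
LUNGALE
SIBADI
VULABE
NTAFUPE
NKAMISO
KHAKGONDO
MPODUYO
SEWEKA
KHANGAPE
GAHLAPE
THADUYO
MAPOMU
VUSHADI
MOMIDI
ZAPOWA
KHAMESWA
NKAKGOLA
GAMEZWE
MPOMILA
NOLANI
LUHLAWA
VUPOYO
PHUKGOKA
SIMIDI
SIKHUTU
NKADUYO
MPOTSOWA
LUBAZWE
KHADULE
NONDINA
LEBAWA
NKALOLA
KHABAMBI
KUZINDO
LEBADI
SIRENDO
KHARENI
TSHELAWA
SILOMBI
PHUNDILA
GAPOMU
NOSHAKO
LUPOSO
BOFUWA
MAWEPE
MATSOWA
KUSHANI
ZADUNA
LUNDINDO
ZALAZWE
LULAWA
NTAZIBE
MANYAPE
GALONI
VUHLADI
TSHENDIMU
ZALOPE
BONGATSE
MPOSHAZWE
SIMESO
THADUBE
MAMELA
BONDIWA
LUNDILA
BOBATU
SILOKA
KHAHLAKA
SEDUWA
TSHEDUWA
MPOSHASWA
GAPOLE
NKAZIYO
LETSONA
GAMIKA
GATSOTU
MOMINA
MASHANDO
MPOMENDO
THAPOPE
PHUPOTU
NTABASWA
PHUNGASWA
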