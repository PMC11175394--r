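NKOSI
DLAMINI
NDLOVU
KHUMALO
MTHEMBU
ZULU
MOKOENA
MAHLANGU
SITHOLE
NGCOBO
MKHIZE
CELE
ZUNGU
GUMEDE
BUTHELEZI
SHABALALA
MASEKO
SIBIYA
MABASO
RADEBE
HADEBE
MAZIBUKO
VILAKAZI
TSHABALALA
MOLEFE
MOTAUNG
MOFOKENG
KHOZA
NGWENYA
SIKHOSANA
MNGUNI
MBATHA
VAN DER MERWE
BOTHA
PRETORIUS
VAN WYK
VENTER
COETZEE
FOURIE
DU PLESSIS
STEYN
KRUGER
NEL
SWANEPOEL
VAN ZYL
JOUBERT
MEYER
SMIT
SMITH
JONES
BROWN
WILLIAMS
TAYLOR
DAVIDS
ADAMS
PETERSEN
HENDRICKS
JACOBS
ABRAHAMS
FEBRUARY
SEPTEMBER
OCTOBER
APRIL
JANTJIES
NAIDOO
PILLAY
GOVENDER
MOODLEY
REDDY
SINGH
MAHARAJ
RAMPERSAD
CHETTY
NAICKER
PADAYACHEE
MOONSAMY
KHAN
ISMAIL
EBRAHIM
DAWOOD
MTHETHWA
XABA
DUBE
NXUMALO
MYENI
NTULI
MCHUNU
MADONSELA
SELEPE
RAMAPHOSA
MODISE
TAU
PHIRI
BANDA
MOYO
NCUBE
MATHEBULA
BALOYI
CHAUKE
NKUNA
MALULEKE
RIKHOTSO
NOVELA
SHIRINDA
MOGALE
MOLOI
LEKOTA
SEKHUKHUNE
MASHABA
MAKGOBA
RAMORWA
PITSE
QWABE
MAJOLA
NGEMA
SHEZI
ZWANE
NZIMANDE
MSOMI
LUTHULI
BESTER
BARNARD
ERASMUS
VILJOEN
OLIVIER
MARAIS
ROUX
THERON
FERREIRA
GROBLER
LOMBARD
SCHOEMAN
STANDER
VORSTER
WESSELS
BEZUIDENHOUT
GQOBA
MADIKIZELA
MATANZIMA
SOGA
JORDAN
MAKELENI
QUNTA
TYALI
WITBOOI
PLAATJIES
FORTUIN
SOLOMONS
DAMON
CUPIDO
LOUW
SAMUELS
KEKANA
MAHLO
RAMPHELE
SEBOKA
TLADI
MONARENG
MASHIANE
LEDWABA
LULANA
ZALASWA
NTAHLAMU
GAMEMBI
PHUPONI
THAMILA
SIPOTU
LUTHEZWE
BOLOSWA
MOKHULE
TSHENYALA
ZAPOBE
NORETU
DIPOLA
PHUNDIBE
BORELA
PHUFUDI
SINDITU
DINGAPE
SIHLAMU
DIPOSO
NOMEMBI
NTAFUNDO
MPODUBE
THAKGOZWE
LELANI
DIMEWA
DIKHUDI
LUNYASO
THATHEKO
TSHENYAMU
KUBADI
SIHLAPE
LUSHADI
SIRELA
THARENA
LUDUDI
NKATSOSO
NKATHEYO
SINGAWA
LEFUNI
TSHEHLAZWE
LUPOLA
ZAKGOPE
TSHEMIYO
SEZIKA
MOBAMBI
TSHEMINDO
PHUDUKA
KHAPOTSE
KHABABE
MPOWETU
VUKHUZWE
TSHEKHUTSE
NKALOSWA
MPOKHUPE
MOKGOZWE
MATHELE
LUNYAMU
SINGATU
NKALOWA
DIHLAPE
MAHLALA
TSHEHLANDO
THALOKA
PHUFUNDO
NTANGAPE
GAHLASWA
MATHEMBI
MPOFUZWE
NOLAKA
LEHLABE
TSHELAZWE
NTABAZWE
NKAKHUDI
SEWEKA
NTANGASWA
NKAZIKA
BONDIMBI
SEMEKA
NTAMITHI
VUTSOWA
MPOMISO
MPOZILA
MADUTHI
GALOWA
LUREPE
MOLOBE
MAMESWA
TSHESHAWA
MOPOLE
SELOZWE
LUREKO
SEDUKO
SELAKA
NOSHATHI
DILONDO
TSHETSONDO
SEPOMBI
SINGALA
GAREPE
MOKHUNI
KUZINDO
NTANGASO
BOHLAMU
DINGAKO
NTAZIMBI
NKAMIZWE
SEFUSWA
ZABABE
TSHELAPE
NOBAPE
DIFUYO
TSHENDINA
NTATHEZWE
TSHEPOTU
NKAMEBE
GATHENA
NKAFULE
MPOLAZWE
MOTSOYO
NKAMEPE
MAWELA
SITHEKA
VUBAMU
MADUSWA
ZAMILE
MAMETHI
THAMIYO
GATSOMU
SENYATHI
NKABATSE
LUKHULE
THAMIWA
VUTHEMU
PHUNDIKA
ZANYAYO
VUPONI
NKAMINDO
MPOPOWA
MPOWEMBI
NKANDINDO
THAKGOKO
LUNGAMU
KUMINI
KUBATSE
PHUNGANDO
SERETU
KHASHANI
LULAKO
NOBATHI
PHUKHUNI
ZAPOLE
NOMETU
SEMIMBI
VUMIWA
NTANDIBE
PHUDUTSE
LEMEPE
NOLOTU
ZANYATSE
PHUBAZWE
KHAFUTHI
MPOZIMBI
NONDIMBI
TSHEKGODI
SIDUBE
KHANDITU
LEMINA
NTALATU
LEBAPE
TSHEBAPE
THAKGOYO
NOPOMBI
NTAWETHI
GAKGOSWA
DILOLE
KHASHAMU
TSHEPOSO
VULASO
DIMILE
LUSHAWA
LUFUZWE
TSHESHADI
MPOBALE
MOKGOTHI
MPOLOTSE
THANYAZWE
KUMIYO
MONDIDI
TSHEBAZWE
SENYADI
KULATHI
GABABE
NONDIYO
SEKHUPE
THAKGOPE
GALALA
GALONA
KUPOKO
BOTSOKA
SEPOKA
SELAWA
DILATSE
SEHLABE
LEPOSO
KULASWA
LUKGOMU
NTAMIMBI
SITHEZWE
SIRETHI
LUFUNA
LENYALE
MPOMEDI
KHATSONI
NKALODI
VUFUMU
ZALOZWE
GANYALA
NTATHELE
GAMIDI
TSHEKGOWA
LEWEKA
KUNDIKA
NORELE
LULABE
SIBANI
DIMEKO
LUBAKA
MOTHEDI
DINDIPE
NOLONA
DITSOKO
SESHATSE
LUDUPE
KHATSOBE
SIZINA
MARETU
LEPOLE
MPOWETHI
SEDUZWE
KHAKGOSO
SITHESO
LEMETSE
LUHLASWA
ZANYANI
DIMIKO
SILAMU
LUKGODI
MOLONA
NOMEKA
NONGAMBI
LENYAZWE
PHUBAKA
NKAWEKA
ZADUSO
SIBAZWE
MAKHUZWE
GAPOLA
ZASHASO
NONDIKO
GANYAWA
KHAREZWE
PHULASWA
PHUMIKO
VULOZWE
KUMENI
GALOSO
MOWENI
LEMEKA
SIREPE
BOZILA
MAMIMU
NTAHLAPE
MOMIDI
GATSOZWE
LUPOBE
THADUKO
THABAMU
THASHASWA
KHATSODI
SEHLAMBI
KULOZWE
LUNDIMU
KULAWA
KUFUKA
VUSHASWA
TSHEPONA
NTATSOLA
LEKHUTU
ZALONDO
SIMEPE
SEBAMU
BOWESWA
MOMIZWE
THADUSO
SIKHUSWA
NOFUKO
KUDUPE
BOZIYO
DIKHUPE
MAZIDI
PHUFUZWE
NKADUTU
SETSOPE
LEFULA
KHATSOSO
THANYADI
NKABAMU
VUZILA
NOTSOMBI
BOFUYO
MPOTHENA
GAHLALA
NONDIPE
VUWELA
NOWEKA
NKAHLATHI
GAKHUKO
KHANYADI
PHULATHI
MOLATSE
GANDITHI
ZARESO
NOMETHI
DIFULE
KUHLATHI
VUMEDI
NOTHEKO
GALASO
SELONI
THAFUDI
VULAKO
SERELA
NKAMENA
NKADUPE
NKALAZWE
BOLOMBI
PHUDUNI
PHUMINDO
LENGANA
TSHEMEMBI
MPOKHUWA
MOBAKA
KHASHASWA
VULOSWA
NTAMEDI
MANDIZWE
NOKHUKA
SENDIWA
LUMENDO
NOSHADI
NOTSODI
DINDIMBI
ZANYAZWE
MOBAZWE
TSHEHLALA
SEMIZWE
NTAPOKA
SIREZWE
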