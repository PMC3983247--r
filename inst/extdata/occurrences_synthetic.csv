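"id","lat","lon","source"
"occ-001",17.2208153489046,62.023258917965,"GBIF"
"occ-002",10.6382531016134,56.9046842223033,"GBIF"
"occ-003",15.5018422370777,48.020879464224,"survey"
"occ-004",8.01479530613869,61.0563309174031,"literature"
"occ-005",12.2917958954349,44.3215342899784,"GBIF"
"occ-006",17.5924459355883,53.9654566822574,"literature"
"occ-007",,,"GBIF"
"occ-008",18.8145586699247,55.1619465611875,"literature"
"occ-009",20.1097582094371,59.758944391273,"literature"
"occ-010",13.1236313972622,49.0984836230054,"MBG"
"occ-011",14.1873097666539,53.5751395262778,"survey"
"occ-012",,,"GBIF"
"occ-013",17.2036659079604,60.5803273394704,"GBIF"
"occ-014",21.5792861888185,59.3021984826773,"literature"
"occ-015",12.0441637099721,62.2361510070041,"GBIF"
"occ-016",7.93253368651494,49.7296575279906,"GBIF"
"occ-017",,,"MBG"
"occ-018",,,"MBG"
"occ-019",22.3496253141202,47.0156347714365,"literature"
"occ-020",,,"MBG"
"occ-021",9.33233001083136,44.061371801421,"GBIF"
"occ-022",15.8458787561394,62.1176232034341,"GBIF"
"occ-023",11.4107829672284,54.7966142008081,"MBG"
"occ-024",22.9468302195892,53.4936395296827,"GBIF"
"occ-025",9.80216328939423,55.6746458318084,"GBIF"
"occ-026",23.3081860681996,51.5255106808618,"GBIF"
"occ-027",13.7919084504247,56.7832003962249,"literature"
"occ-028",8.70394001668319,57.9363097865134,"literature"
"occ-029",17.4864014829509,54.4627699544653,"GBIF"
"occ-030",14.1452133217826,62.7594520766288,"MBG"
"occ-031",7.52301769796759,50.3380522653461,"MBG"
"occ-032",19.1690265219659,60.8106319988146,"GBIF"
"occ-033",8.5941363601014,56.8151578176767,"GBIF"
"occ-034",21.5060010971501,59.5033132946119,"GBIF"
"occ-035",,,"MBG"
"occ-036",18.1146279000677,48.2499545728788,"GBIF"
"occ-037",18.7429839558899,53.5343421446159,"MBG"
"occ-038",22.1099708606489,55.3514776481315,"MBG"
"occ-039",22.1099113491364,54.5428888974711,"GBIF"
"occ-040",17.63813693868,56.873722454533,"GBIF"
"occ-041",7.43103244621307,57.6178327677771,"literature"
"occ-042",23.1531563275494,47.968624570407,"GBIF"
"occ-043",6.46074072830379,60.0340712452307,"GBIF"
"occ-044",20.1025954666547,45.7353487526998,"literature"
"occ-045",23.1522263679653,44.7745992671698,"survey"
"occ-046",14.12336762622,62.1705442024395,"literature"
"occ-047",6.35834666993469,44.4797481326386,"survey"
"occ-048",,,"literature"
"occ-049",8.59521501045674,54.74317894876,"GBIF"
"occ-050",16.3793455199338,60.2960138125345,"literature"
"occ-051",19.9217793834396,61.6350650424138,"survey"
"occ-052",12.5506899598986,59.6756546674296,"GBIF"
"occ-053",17.0355376498774,57.086250773631,"GBIF"
"occ-054",,,"GBIF"
"occ-055",19.3171415780671,50.5781822288409,"literature"
"occ-056",20.7412705421448,60.3595641544089,"GBIF"
"occ-057",15.8391571864486,51.8042719978839,"GBIF"
"occ-058",11.6280638161115,57.1297443900257,"MBG"
"occ-059",13.5689995642751,53.0820506261662,"GBIF"
"occ-060",,,"MBG"
"occ-061",,,"MBG"
"occ-062",21.7520423512906,55.9461681554094,"literature"
"occ-063",9.32151329051703,45.1835863115266,"GBIF"
"occ-064",19.1792388274334,47.2654569484293,"GBIF"
"occ-065",22.9451652844436,63.0645350841805,"GBIF"
"occ-066",20.1507732253522,55.6419389471412,"literature"
"occ-067",12.8551833378151,63.7364374622703,"literature"
"occ-068",10.8667078446597,52.9279060577974,"literature"
"occ-069",6.77471760101616,52.0976602761075,"MBG"
"occ-070",,,"literature"
"occ-071",10.8543728641234,53.3829977372661,"MBG"
"occ-072",12.8805758818053,55.076099560596,"GBIF"
"occ-073",22.3919682414271,59.7570135453716,"GBIF"
"occ-074",14.1711593144573,47.6818944988772,"GBIF"
"occ-075",12.4991138591431,49.1699268538505,"literature"
"occ-076",23.7594578485005,47.756527742371,"literature"
"occ-077",21.668732851278,52.1580829620361,"MBG"
"occ-078",18.6003433722071,53.4628242542967,"GBIF"
"occ-079",10.1690308805555,55.0669754818082,"literature"
"occ-080",21.6096404800192,47.9641226548702,"MBG"
"occ-081",13.2369269127958,52.1136983400211,"literature"
"occ-082",7.00285924226046,48.2055442463607,"GBIF"
"occ-083",,,"MBG"
"occ-084",9.42973555019125,50.6622326429933,"GBIF"
"occ-085",,,"MBG"
"occ-086",22.203962970525,56.0601216424257,"GBIF"
"occ-087",15.7746012182906,59.8105893013999,"MBG"
"occ-088",11.6367606734857,61.2634123684838,"literature"
"occ-089",22.2047257572412,54.6701690331101,"GBIF"
"occ-090",18.4992432156578,63.2336629983038,"GBIF"
"occ-091",18.5096801267937,61.1732700848952,"MBG"
"occ-092",21.095331276767,46.7853589365259,"GBIF"
"occ-093",11.7040503574535,54.0749143026769,"GBIF"
"occ-094",18.6959856441244,50.3375088339671,"literature"
"occ-095",19.04645712208,47.3468621456996,"MBG"
"occ-096",9.67472408758476,57.2612775731832,"literature"
"occ-097",15.9100290904753,54.1899990346283,"literature"
"occ-098",7.16922010481358,54.9771238127723,"literature"
"occ-099",13.9957206831314,46.3699776129797,"GBIF"
"occ-100",,,"GBIF"
"occ-101",20.341858824715,62.3623743150383,"survey"
"occ-102",16.0685462183319,53.2404860258102,"literature"
"occ-103",14.640549743548,59.2796177379787,"GBIF"
"occ-104",19.8614625921473,53.685657392256,"GBIF"
"occ-105",6.18705005664378,44.2680345019326,"GBIF"
"occ-106",14.4114543842152,44.2750689256936,"GBIF"
"occ-107",15.6516066924669,51.1867014886811,"MBG"
"occ-108",6.48328635049984,61.572568776086,"GBIF"
"occ-109",19.2909987070598,63.1725111985579,"GBIF"
"occ-110",18.5980417057872,50.9772781338543,"GBIF"
"occ-111",16.9184921002015,48.5749154081568,"survey"
"occ-112",9.62908250838518,52.4793125092983,"survey"
"occ-113",11.5957354274578,44.415396229364,"GBIF"
"occ-114",19.7546517318115,46.8840171545744,"MBG"
"occ-115",19.5191265642643,59.4897711984813,"MBG"
"occ-116",10.9198611890897,49.4319700086489,"literature"
"occ-117",20.8490572026931,53.2332215094939,"GBIF"
"occ-118",10.282426211983,61.7076237928122,"literature"
"occ-119",10.5235014860518,53.8141926666722,"MBG"
"occ-120",15.2924037566409,52.6825888743624,"GBIF"
"occ-121",22.0759152802639,47.8103528693318,"GBIF"
"occ-122",10.1715082819574,54.8043781714514,"survey"
"occ-123",17.9359514066018,62.5282321693376,"GBIF"
"occ-124",6.10965683497488,62.5889559751377,"survey"
"occ-125",14.4020834835246,49.8737028390169,"survey"
"occ-126",22.7995384004898,56.1650844579563,"literature"
"occ-127",14.0941855777055,60.9943251879886,"survey"
"occ-128",6.63710233708844,60.3143223896623,"MBG"
"occ-129",10.1957456865348,61.2244346747175,"literature"
"occ-130",10.7252237624489,52.0404015583917,"survey"
"occ-131",15.1009670938365,46.567054014653,"GBIF"
"occ-132",23.0200876635499,59.4636336350814,"literature"
"occ-133",,,"literature"
"occ-134",14.8206260106526,45.4048519078642,"GBIF"
"occ-135",,,"literature"
"occ-136",23.9241525898688,60.3366892607883,"literature"
"occ-137",12.4439655211754,48.3234422476962,"survey"
"occ-138",,,"GBIF"
"occ-139",6.88621110375971,52.4240080881864,"literature"
"occ-140",,,"GBIF"
"occ-141",6.242045823019,62.0076384078711,"GBIF"
"occ-142",9.06921235565096,58.8846482206136,"GBIF"
"occ-143",,,"GBIF"
"occ-144",21.0108402678743,54.4114827513695,"literature"
"occ-145",11.7263847179711,60.0743356170133,"GBIF"
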