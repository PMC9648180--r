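 &FCI NORB=5,NELEC=4,MS2=2,
  ORBSYM=1,1,1,1,1,
  ISYM=1,
 &END
  2.3196876883248940E-01   1   1   1   1
  2.3484482256036499E-02   2   1   1   1
  5.1844277384381646E-02   2   1   2   1
  7.6472420769468252E-02   2   2   1   1
 -1.4229634705785579E-01   2   2   2   1
 -2.3551391387229789E-01   2   2   2   2
 -1.9203330191592727E-01   3   1   1   1
 -1.7579044752187889E-01   3   1   2   1
 -7.1122729615195956E-01   3   1   2   2
 -2.8334996855482497E-01   3   1   3   1
 -8.9753853198413155E-02   3   2   1   1
 -1.5519354112104952E-01   3   2   2   1
 -1.6636561041651099E-01   3   2   2   2
  1.0366023278640992E-02   3   2   3   1
 -1.2331026228508651E-01   3   2   3   2
  5.0879350185188549E-02   3   3   1   1
 -6.6304092287156599E-02   3   3   2   1
 -4.1263862894562353E-02   3   3   2   2
  2.4306741727347003E-01   3   3   3   1
  3.7841128376709510E-01   3   3   3   2
  1.4838704227132689E-02   3   3   3   3
  3.5033923388783345E-01   4   1   1   1
 -4.6297487351407367E-02   4   1   2   1
  1.0869049695225518E-01   4   1   2   2
 -1.9780028023475926E-01   4   1   3   1
  6.3106292769354616E-02   4   1   3   2
  4.8846549284462198E-01   4   1   3   3
  1.0993857230428816E-01   4   1   4   1
 -5.8486734642090336E-03   4   2   1   1
 -1.6615667553614355E-01   4   2   2   1
  2.4928687723231666E-01   4   2   2   2
 -2.7515105823793296E-01   4   2   3   1
 -6.6221689504161518E-02   4   2   3   2
  1.9618229722153585E-01   4   2   3   3
  4.3815411282822869E-01   4   2   4   1
  6.1091493500354914E-03   4   2   4   2
 -1.5710348114999745E-01   4   3   1   1
  6.5088111223087941E-02   4   3   2   1
 -1.7616870998857792E-01   4   3   2   2
  4.1865188613806024E-02   4   3   3   1
  3.0206590486842207E-02   4   3   3   2
 -6.8695758895950101E-02   4   3   3   3
  1.8117551923231534E-01   4   3   4   1
  1.8379097076294915E-01   4   3   4   2
 -1.1119749840777293E-01   4   3   4   3
  1.1204696826079721E-01   4   4   1   1
 -3.5848355916125552E-01   4   4   2   1
 -3.1308337301752409E-01   4   4   2   2
 -6.6406377614806944E-01   4   4   3   1
  3.0944314260212102E-02   4   4   3   2
 -7.2925332083532621E-02   4   4   3   3
 -4.8673677074242994E-01   4   4   4   1
  6.7292861082021746E-02   4   4   4   2
 -1.2809056398487736E-01   4   4   4   3
  3.6422408343954665E-01   4   4   4   4
 -3.6934469086077909E-01   5   1   1   1
  1.2834336730854931E-01   5   1   2   1
  2.3710497385419652E-01   5   1   2   2
 -3.5537605968456530E-02   5   1   3   1
 -2.5722518482688167E-01   5   1   3   2
  9.2690128818654960E-02   5   1   3   3
  1.7613325472214558E-01   5   1   4   1
  2.7884390941291914E-02   5   1   4   2
 -7.5010965569356755E-02   5   1   4   3
  8.5078067223643486E-03   5   1   4   4
  1.2677605813645285E-01   5   1   5   1
 -3.4149769191515333E-01   5   2   1   1
  3.9373091879751701E-03   5   2   2   1
 -5.9759273406313033E-02   5   2   2   2
 -8.8352565090411728E-02   5   2   3   1
  1.1819506316810391E-01   5   2   3   2
 -2.2686416166049286E-01   5   2   3   3
 -8.7748917560991527E-02   5   2   4   1
  6.8980273742483805E-02   5   2   4   2
 -8.9880074023066830E-02   5   2   4   3
  8.7640443060221715E-03   5   2   4   4
 -1.1359831719772247E-01   5   2   5   1
  3.6497206152035305E-01   5   2   5   2
  8.6600513902004350E-02   5   3   1   1
 -2.7079325537966276E-01   5   3   2   1
  2.3089318112909052E-01   5   3   2   2
  1.8414738955627030E-01   5   3   3   1
 -8.9731492687589731E-02   5   3   3   2
  4.1411474321167774E-01   5   3   3   3
 -3.9911225711442178E-02   5   3   4   1
 -2.2582569904852551E-01   5   3   4   2
 -2.5911097298214553E-01   5   3   4   3
  2.4808377539068627E-01   5   3   4   4
  3.3901174464672429E-01   5   3   5   1
  1.0046018781958979E-01   5   3   5   2
  6.6726329911590263E-02   5   3   5   3
 -1.0164052602886689E-01   5   4   1   1
 -7.4126470433774558E-02   5   4   2   1
  3.0172859037659222E-01   5   4   2   2
 -9.9251572088249473E-03   5   4   3   1
  2.7635132493098602E-01   5   4   3   2
  8.9786485345349137E-02   5   4   3   3
 -3.0461991045215121E-02   5   4   4   1
  5.1858795165682793E-02   5   4   4   2
 -3.2228033304637393E-01   5   4   4   3
 -4.0179119815493219E-01   5   4   4   4
 -3.9987424822725925E-01   5   4   5   1
  2.4208135270988432E-02   5   4   5   2
 -4.5998960089447281E-02   5   4   5   3
 -4.3982041519676401E-01   5   4   5   4
 -3.4208171362099415E-01   5   5   1   1
  4.5251838943213468E-02   5   5   2   1
  1.9017005167245893E-01   5   5   2   2
  4.2168310876337450E-01   5   5   3   1
 -1.2424523859528380E-01   5   5   3   2
  2.1092949225433189E-01   5   5   3   3
 -3.2780189097231449E-01   5   5   4   1
  1.6819663871155077E-01   5   5   4   2
 -1.0509500101171672E-01   5   5   4   3
  1.2771709081912212E-02   5   5   4   4
 -9.2730474008102734E-02   5   5   5   1
  1.3220894689483922E-01   5   5   5   2
 -8.7997218173849326E-02   5   5   5   3
 -5.7631907765401919E-02   5   5   5   4
 -2.6318966250594605E-01   5   5   5   5
 -1.0150087164606165E+00   1   1   0   0
 -1.2262433622528304E-01   2   1   0   0
  9.7287442610436436E-01   2   2   0   0
  4.7390110714742240E-01   3   1   0   0
  1.1798630240993544E+00   3   2   0   0
  1.2953218674674050E+00   3   3   0   0
 -4.3622349529201765E-01   4   1   0   0
  5.4685406256772562E-01   4   2   0   0
  1.7364409927204283E-01   4   3   0   0
  6.2595440154527804E-01   4   4   0   0
  7.2655924392436166E-01   5   1   0   0
 -1.5772612277145029E-01   5   2   0   0
  4.3397418055859222E-01   5   3   0   0
  1.1535553449638392E+00   5   4   0   0
 -5.9575563245483121E-01   5   5   0   0
  1.7102272563645231E+00   0   0   0   0
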