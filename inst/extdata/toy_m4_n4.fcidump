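 &FCI NORB=4,NELEC=4,MS2=0,
  ORBSYM=1,1,1,1,
  ISYM=1,
 &END
 -5.6850584283214482E-02   1   1   1   1
 -5.3129108418095516E-01   2   1   1   1
 -4.8809338571510391E-01   2   1   2   1
  2.6402266914603845E-01   2   2   1   1
 -6.1327718815694911E-02   2   2   2   1
 -3.5626168679600001E-01   2   2   2   2
 -3.4383471151924271E-02   3   1   1   1
  2.4293493983451975E-01   3   1   2   1
  3.7903869225299308E-01   3   1   2   2
 -8.6093826321239936E-02   3   1   3   1
 -5.1453876553785929E-02   3   2   1   1
 -3.5263261703895604E-01   3   2   2   1
  9.2019470966254291E-02   3   2   2   2
 -1.2799897519202383E-01   3   2   3   1
  9.1090024648243881E-02   3   2   3   2
  1.4096746744576383E-01   3   3   1   1
  2.0702070439398446E-01   3   3   2   1
 -1.2178527508144221E-01   3   3   2   2
  1.0099102465959407E-01   3   3   3   1
 -3.4340173581466854E-01   3   3   3   2
 -1.5689180167589922E-01   3   3   3   3
 -1.7018151883530366E-01   4   1   1   1
 -4.8284152998932639E-01   4   1   2   1
  7.2245213784511266E-03   4   1   2   2
  4.1199720040050770E-02   4   1   3   1
 -7.2211459709733264E-02   4   1   3   2
  1.5163264713990340E-01   4   1   3   3
 -1.4534096541531505E-01   4   1   4   1
 -2.7365620888385894E-01   4   2   1   1
  8.6563605177743433E-02   4   2   2   1
 -1.6227863523733432E-01   4   2   2   2
  2.8882025234425057E-01   4   2   3   1
 -8.6289240522669092E-02   4   2   3   2
  1.3112957668044137E-01   4   2   3   3
  6.4385053040789314E-02   4   2   4   1
 -1.5676778817607509E-01   4   2   4   2
  3.1514550395839547E-01   4   3   1   1
  1.2857986114346329E-01   4   3   2   1
  1.7952129319921135E-02   4   3   2   2
  5.5310149458292601E-02   4   3   3   1
  1.3585776321105417E-01   4   3   3   2
  1.7966577315816339E-02   4   3   3   3
 -5.9861801663058700E-01   4   3   4   1
  5.6976590706131883E-02   4   3   4   2
 -7.3446928548195067E-02   4   3   4   3
  3.7046112973121867E-02   4   4   1   1
  1.1636474547310134E-01   4   4   2   1
  2.7994736545853566E-01   4   4   2   2
 -1.4545841189489303E-01   4   4   3   1
  2.6050852640882877E-01   4   4   3   2
  6.7169623950414897E-02   4   4   3   3
  2.0770121973952424E-01   4   4   4   1
  1.8414571365812926E-01   4   4   4   2
  1.4417563257337249E-01   4   4   4   3
 -2.0862378771357101E-01   4   4   4   4
  1.3709584471466685E+00   1   1   0   0
 -8.0214924127544829E-02   2   1   0   0
 -1.0612451609148403E-01   2   2   0   0
  1.1907760626071906E+00   3   1   0   0
  7.2440394919325890E-01   3   2   0   0
  1.3048696542234852E+00   3   3   0   0
 -3.7799904807564944E-01   4   1   0   0
 -1.8672390261523447E-01   4   2   0   0
  1.0766620281537245E+00   4   3   0   0
  6.3595039807007436E-01   4   4   0   0
 -9.0186386610706687E-02   0   0   0   0
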