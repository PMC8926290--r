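# cc-pVDZ correlation-consistent double-zeta basis (published
# exponents/coefficients; coefficients refer to normalized primitives).
# d shells are used in their 6-component Cartesian form by this package.
element H
shell S
  13.0100000   0.0196850
   1.9620000   0.1379770
   0.4446000   0.4781480
   0.1220000   0.5012880
shell S
   0.1220000   1.0000000
shell P
   0.7270000   1.0000000
element He
shell S
  38.3600000   0.0238090
   5.7700000   0.1548910
   1.2400000   0.4699870
   0.2976000   0.5130270
shell S
   0.2976000   1.0000000
shell P
   1.2750000   1.0000000
element C
shell S
  6665.0000000   0.0006920
  1000.0000000   0.0053290
   228.0000000   0.0270770
    64.7100000   0.1017180
    21.0600000   0.2747400
     7.4950000   0.4485640
     2.7970000   0.2850740
     0.5215000   0.0152040
     0.1596000  -0.0031910
shell S
  6665.0000000  -0.0001460
  1000.0000000  -0.0011540
   228.0000000  -0.0057250
    64.7100000  -0.0233120
    21.0600000  -0.0639550
     7.4950000  -0.1499810
     2.7970000  -0.1272620
     0.5215000   0.5445290
     0.1596000   0.5804960
shell S
     0.1596000   1.0000000
shell P
     9.4390000   0.0381090
     2.0020000   0.2094800
     0.5456000   0.5085570
     0.1517000   0.4688420
shell P
     0.1517000   1.0000000
shell D
     0.5500000   1.0000000
element N
shell S
  9046.0000000   0.0007000
  1357.0000000   0.0053890
   309.3000000   0.0274060
    87.7300000   0.1032070
    25.5600000   0.2787230
     8.5730000   0.4485400
     2.7720000   0.2782380
     0.6605000   0.0154400
     0.2067000  -0.0028640
shell S
  9046.0000000  -0.0001530
  1357.0000000  -0.0012080
   309.3000000  -0.0059920
    87.7300000  -0.0245440
    25.5600000  -0.0674590
     8.5730000  -0.1580780
     2.7720000  -0.1218310
     0.6605000   0.5490030
     0.2067000   0.5788150
shell S
     0.2067000   1.0000000
shell P
    13.5500000   0.0399190
     2.9170000   0.2171690
     0.7973000   0.5103190
     0.2185000   0.4622140
shell P
     0.2185000   1.0000000
shell D
     0.8170000   1.0000000
element O
shell S
  11720.0000000   0.0007100
   1759.0000000   0.0054700
    400.8000000   0.0278370
    113.7000000   0.1048000
     37.0300000   0.2830620
     13.2700000   0.4487190
      5.0250000   0.2709520
      1.0130000   0.0154580
      0.3023000  -0.0025850
shell S
  11720.0000000  -0.0001600
   1759.0000000  -0.0012630
    400.8000000  -0.0062670
    113.7000000  -0.0257160
     37.0300000  -0.0709240
     13.2700000  -0.1654110
      5.0250000  -0.1169550
      1.0130000   0.5573680
      0.3023000   0.5727590
shell S
      0.3023000   1.0000000
shell P
     17.7000000   0.0430180
      3.8540000   0.2289130
      1.0460000   0.5087280
      0.2753000   0.4605310
shell P
      0.2753000   1.0000000
shell D
      1.1850000   1.0000000
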