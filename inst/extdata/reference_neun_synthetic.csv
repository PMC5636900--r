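"depth_lo","depth_hi","neurons_per_column"
0,50,40
50,100,60
100,150,300
150,200,480
200,250,600
250,300,650
300,350,650
350,400,640
400,450,620
450,500,600
500,550,580
550,600,560
600,650,800
650,700,900
700,750,1000
750,800,980
800,850,900
850,900,820
900,950,700
950,1000,680
1000,1050,660
1050,1100,640
1100,1150,620
1150,1200,600
1200,1250,580
1250,1300,560
1300,1350,540
1350,1400,520
1400,1450,560
1450,1500,580
1500,1550,560
1550,1600,520
1600,1650,460
1650,1700,400
1700,1750,340
1750,1800,280
1800,1850,220
1850,1900,120
1900,1950,60
1950,2000,20
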