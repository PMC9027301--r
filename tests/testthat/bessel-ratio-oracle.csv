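x_re,x_im,ratio_re,ratio_im
0.0001,0.0,20000.000025,0.0
9.8078528040323045e-5,1.9509032201612827e-5,19615.705632584241,-3901.8064354453073
9.2387953251128676e-5,3.8268343236508977e-5,18477.590673322723,-7653.6686377347096
8.3146961230254524e-5,5.5557023301960222e-5,16629.392266837645,-11111.404646502789
7.0710678118654752e-5,7.0710678118654752e-5,14142.13564140862,-14142.135606053281
0.00031622776601683793,0.0,6324.5553993936998,0.0
0.00031015153816411154,6.1692976702665776e-5,6203.0308408201151,-1233.8595186300715
0.0002921563606347248,0.00012101512690846803,5843.1272857335861,-2420.3025079155792
0.00026293377800932023,0.0001756867336532429,5258.6756259198491,-3513.7346291431749
0.00022360679774997897,0.00022360679774997897,4472.1360109012791,-4472.1358990978802
0.001,0.0,2000.0002499999896,0.0
0.00098078528040323045,0.00019509032201612827,1961.5708060027723,-390.18059525968182
0.00092387953251128676,0.00038268343236508977,1847.7592959924527,-765.36676905933108
0.00083146961230254524,0.00055557023301960222,1662.9394324724956,-1111.1403271466564
0.00070710678118654752,0.00070710678118654752,1414.2137391497977,-1414.2133855964071
0.0031622776601683793,0.0,632.4563226027615,0.0
0.0031015153816411154,0.00061692976702665776,620.3038517067946,-123.3857991730728
0.002921563606347248,0.0012101512690846803,584.31345166022513,-242.02995127942312
0.0026293377800932023,0.001756867336532429,525.86821335314974,-351.37302808997474
0.0022360679774997897,0.0022360679774997897,447.21415451718524,-447.21303648319649
0.01,0.0,200.0024999895834,0.0
0.0098078528040323045,0.0019509032201612827,196.15950803518599,-39.017576683207749
0.0092387953251128676,0.0038268343236508977,184.77821619710232,-76.535729774060727
0.0083146961230254524,0.0055557023301960222,166.29600113657193,-111.1126576885544
0.0070710678118654752,0.0070710678118654752,141.42312401162812,-141.41958847772228
0.031622776601683793,0.0,63.253458568134671,0.0
0.031015153816411154,0.0061692976702665776,62.038061147398497,-12.337053199105486
0.02921563606347248,0.012101512690846803,58.438575909895527,-24.200000307831417
0.026293377800932023,0.01756867336532429,52.593329010557604,-35.13295488537775
0.022360679774997897,0.022360679774997897,44.726949952848732,-44.715769612990349
0.1,0.0,20.024989589839413,0.0
0.098078528040323045,0.019509032201612827,19.640216582549041,-3.8969349640531298
0.092387953251128676,0.038268343236508977,18.500683649765342,-7.6441111792246199
0.083146961230254524,0.055557023301960222,16.650181012166415,-11.097525619806166
0.070710678118654752,0.070710678118654752,14.159820654349625,-14.124465324497413
0.31622776601683793,0.0,6.403284903059692,0.0
0.31015153816411154,0.061692976702665776,6.2802958995695756,-1.2186175984542368
0.2921563606347248,0.12101512690846803,5.9160394701651993,-2.3903511892123079
0.26293377800932023,0.1756867336532429,5.3244712566666929,-3.4701356511888164
0.22360679774997897,0.22360679774997897,4.5282691127723071,-4.4164686253127454
1.0,0.0,2.2401937238700897,0.0
0.98078528040323045,0.19509032201612827,2.1984584982556288,-0.34669377741169901
0.92387953251128676,0.38268343236508977,2.0745309843158993,-0.67873582941096543
0.83146961230254524,0.55557023301960222,1.872225839806575,-0.98230379075362071
0.70710678118654752,0.70710678118654752,1.5978671159929846,-1.2452303005115017
3.1622776601683793,0.0,1.217579924222897,0.0
3.1015153816411154,0.61692976702665776,1.2072520860140674,-0.05926018471695528
2.921563606347248,1.2101512690846803,1.1771528180799243,-0.11085314159612152
2.6293377800932023,1.756867336532429,1.1301539828316087,-0.14640845465493538
2.2360679774997897,2.2360679774997897,1.0719879623721224,-0.15524413711367282
10.0,0.0,1.0541853083236816,0.0
9.8078528040323045,1.9509032201612827,1.0528558615841733,-0.011442221124853916
9.2387953251128676,3.8268343236508977,1.0489839035946052,-0.022190724840574824
8.3146961230254524,5.5557023301960222,1.0428902613284117,-0.031645936882607579
7.0710678118654752,7.0710678118654752,1.0350370583500576,-0.039362495790301532
31.622776601683793,0.0,1.0161987677447834,0.0
31.015153816411154,6.1692976702665776,1.0158642553426488,-0.00323511547812624
29.21563606347248,12.101512690846803,1.0148775094534143,-0.0063273954616636848
26.293377800932023,17.56867336532429,1.0132875057019671,-0.0091427745633636549
22.360679774997897,22.360679774997897,1.0111714437094245,-0.011563704309618473
100.0,0.0,1.0050378800081568,-2.7887350431288144e-87
98.078528040323045,19.509032201612827,1.0049388872134769,-0.00099001412984285474
92.387953251128676,38.268343236508977,1.0046460576394893,-0.0019402851221026427
83.146961230254524,55.557023301960222,1.0041716219665693,-0.0028128679380457813
70.710678118654752,70.710678118654752,1.0035352637593902,-0.0035732990094233061
316.22776601683793,0.0,1.0015849007381129,-4.2669154489720311e-275
310.15153816411154,61.692976702665776,1.001554232134036,-0.00030990656966370142
292.1563606347248,121.01512690846803,1.0014634379915669,-0.0006077382903018879
262.93377800932023,175.6867336532429,1.001316101604365,-0.00088190988205005515
223.60679774997897,223.60679774997897,1.0011180255540876,-0.0011217923738142764
1000.0,0.0,1.000500375375493,-5.1569399349419756e-869
980.78528040323045,195.09032201612827,1.0004907394071759,-9.7688875982770815e-5
923.87953251128676,382.68343236508977,1.0004622050748046,-0.00019160722817328287
831.46961230254524,555.57023301960222,1.0004158782389307,-0.00027813193947716601
707.10678118654752,707.10678118654752,1.0003535531249354,-0.00035392865575771823
3162.2776601683793,0.0,1.0001581513948719,-3.8164264740163584e-2747
3101.5153816411154,616.92976702665776,1.000155110424428,-3.0860845571781602e-5
2921.563606347248,1210.1512690846803,1.0001461047013597,-6.0534090919316377e-5
2629.3377800932023,1756.867336532429,1.0001314812373164,-8.7878023943254116e-5
2236.0679774997897,2236.0679774997897,1.0001118033904848,-0.00011184090726024251
10000.0,0.0,1.000050003750375,-2.5788406322455713e-8686
9807.8528040323045,1950.9032201612827,1.0000490427288802,-9.7559513720514298e-6
9238.7953251128676,3826.8343236508977,1.0000461966284195,-1.9136823615187989e-5
8314.6961230254524,5555.7023301960222,1.0000415749156048,-2.7781976567056313e-5
7071.0678118654752,7071.0678118654752,1.0000353553387941,-3.5359089324492413e-5
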