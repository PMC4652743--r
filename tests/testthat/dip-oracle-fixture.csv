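id,n,dip,x
1,2,0.25,0.33007513037104019;1.889124480317697
2,2,0.25,1;2
3,2,0.25,0;0.64242465933784842
4,2,0.25,0.38304638479577341;3.306590893341621
5,2,0.25,0.024366069352254272;0.56059669400565326
6,2,0.25,0.13876510303619205;2.2848037361431022
7,2,0.0,1;1
8,2,0.25,0;1.4379527549350504
9,2,0.25,0.25502315459183539;0.35947904075013698
10,2,0.25,0.33439508639276028;0.6870096658822149
11,3,0.16666666666666666,0.095766954007213176;0.18171795880567387;1.9160134283056642
12,3,0.16666666666666666,0;1;2
13,3,0.16666666666666663,0;0.94406106428317982;2.3854204882869605
14,3,0.16666666666666666,0.15709535556905571;0.7980397149169447;1.4544570790705798
15,3,0.16666666666666666,0.057159162359312177;0.45084113907068968;0.57641476136632264
16,3,0.16666666666666663,-0.22316499719629071;0.13560908646947481;2.3213855666374279
17,3,0.16666666666666666,0;1;2
18,3,0.16666666666666666,0;0.11607007076963782;3.0781719310391433
19,3,0.16666666666666666,0.1207923462765257;0.27490110122676875;2.3785257419339976
20,3,0.16666666666666666,0.08948461152613163;0.55432797898538411;0.88134049531072378
21,4,0.17708449634414952,-0.23403049453102062;0.16863904935366161;1.7943015261010236;2.4636768848342125
22,4,0.125,0;0;1;2
23,4,0.125,0;0;0.88075310825825948;2.9574857947541515
24,4,0.125,0.31322726920498711;0.41345633295116624;0.66190801342183547;5.9023113040739537
25,4,0.125,0.14652827638201416;0.31891885609366;0.36956352484412491;0.51705906423740089
26,4,0.23529316741033912,0.011036025613697474;0.12116183322910321;1.8830537925940931;1.9647867605839242
27,4,0.125,0;1;2;2
28,4,0.125,0;0;0.08431565605010817;1.2632715832021955
29,4,0.125,0.73525192905409265;0.97914412982870958;1.3463264515879623;4.8120085180128971
30,4,0.125,0.4079676631372422;0.71066188812255859;0.74338609119877219;0.76360514922998846
31,5,0.18641660575408983,-0.42878529910728819;-0.26837848525490321;0.29145405867107266;1.9928767414442414;2.1168522584619103
32,5,0.20000000000000007,1;1;1;2;2
33,5,0.19872253632406975,0;0;0.062046802209068996;1.7059319782161955;1.7164994943046812
34,5,0.09999999999999998,0.55866608747923585;0.86984942187491088;1.0212299163781862;1.1236197819668723;1.1812871627857544
35,5,0.17472925213963134,0.33424405893310905;0.38519037421792746;0.73744791792705655;0.75650779460556805;0.89420299371704459
36,5,0.1630937589495276,-0.37389752498106493;0.25205729592949072;0.25366246947593279;1.7102493196885185;2.0398581640191602
37,5,0.2,0;0;1;1;2
38,5,0.1369102515264356,0;0;0.91928508978082835;1.3429017616015795;5.0663913267922203
39,5,0.12473071466138402,0.48590224939545412;0.94325353845900406;1.7011424021511274;1.851142935887325;1.9705128994185763
40,5,0.19418982168343873,0.31171718356199563;0.3248777324333787;0.76473422208800912;0.85884701646864414;0.98429965972900391
41,6,0.2026361976015181,-0.079987208230990633;-0.068097835700214007;-0.022111117184575636;1.7651084784349478;2.0517620241979637;2.1828498137519485
42,6,0.08333333333333333,0;1;1;1;1;2
43,6,0.12460876922294295,0;0;0.21103369851459747;1.1612678709951165;2.9721904843259002;3.5834122949973355
44,6,0.10060680226599916,0.16568593958189473;0.82340305277485104;1.8250826074379838;2.03381025195984;2.7713852405986557;3.7024192463410968
45,6,0.09971265392606075,0.10955481790006161;0.13993924995884299;0.30728534329682589;0.52146463398821652;0.66527950996533036;0.94546553120017052
46,6,0.22163384347371232,0.14226387863407081;0.15288540600977452;0.18716782531597764;1.8167888582172527;1.9139221908333117;2.0253584727368454
47,6,0.16666666666666669,0;1;1;1;2;2
48,6,0.08870392463265336,0;0;0.49957866501063108;1.3498653024014953;2.0971904973170523;3.970198577059866
49,6,0.08854900789431931,0.072515728694381137;0.39399663323484968;0.49333162179856399;0.90004174319458741;1.2588401446446931;2.344684067743517
50,6,0.08333333333333337,0.002091649454087019;0.43646075110882521;0.49947155429981649;0.52963323309086263;0.56837546452879906;0.87008199258707464
51,7,0.18223312167997052,-0.34128331166946463;-0.10497666457285541;0.11480982040896591;0.22306135444967373;1.7417472181742752;1.8029411305855065;2.0088656148593333
52,7,0.14285714285714285,0;0;1;1;1;2;2
53,7,0.12217561176752151,0;0;0;0.024971564535083566;0.88587104127104865;1.0316015928563598;1.5640477705056668
54,7,0.13427631244492694,0.52297163503113064;0.54029742434922445;0.72031339687187723;0.95564178013807599;0.97101154529942946;0.98275025700472729;2.5378878270270349
55,7,0.09412169724261996,0.1365296863950789;0.25248258630745113;0.26563353114761412;0.48867383506149054;0.62335001374594867;0.82124618417583406;0.94269103207625449
56,7,0.20413346224292422,-0.23266157634776569;-0.10653743421992573;-0.085797212746767423;0.050351409476074638;2.0269158015670166;2.1084998500524952;2.1252170779321404
57,7,0.14285714285714285,0;1;1;2;2;2;2
58,7,0.11050024341019027,0;0;0;0.58271683752536774;0.75334913240514312;1.422598128822377;2.2478551695725684
59,7,0.07142857142857142,0.5686778331807697;0.9481365461101412;1.0031877337387773;1.0496114979176296;1.3064380424048787;1.817609510695912;3.006326041677724
60,7,0.1865989970931039,0.054966592229902744;0.17527519399300218;0.23931889422237873;0.25931561132892966;0.84368538460694253;0.92221359047107399;0.93039153469726443
61,8,0.1973692629183971,-0.40200336047192553;-0.04033324750436932;-0.029832548648727461;0.0091696289123300093;1.7147125148691473;1.8389524881179011;1.919185978899077;2.1695147362733183
62,8,0.1875,0;0;0;1;1;1;2;2
63,8,0.07446909398968238,0;0;0;0.20646803592950946;0.60573702165856957;0.87666046801478881;1.7873352392667774;3.1161695774766804
64,8,0.0831855488626064,0.36720436801535455;0.55877257834285898;0.61605579992341275;0.89826496633922714;1.0434846381710783;1.2976447407235485;1.4641873873038298;8.0549258163755688
65,8,0.09139847670350926,0.095928756985813379;0.20910366484895349;0.46855278010480106;0.55493119871243834;0.78988649556413293;0.93330619693733752;0.95070314593613148;0.9596170112490654
66,8,0.19693909497742149,-0.20893563970845191;-0.059974330795808065;0.061986076320529028;0.22218964712906147;1.822339960726844;1.8676246814852955;1.9237506843163177;2.0957561461172602
67,8,0.125,0;1;1;2;2;2;2;2
68,8,0.08631141774807093,0;0;0;0.16247762964751108;0.48470298526808619;0.78683974496544618;0.9491638825820945;2.8341935424316413
69,8,0.0625,0.31026925030408958;0.40369688786766761;0.46139174251044074;0.59971805096103536;0.74007610545348768;1.3880312285480674;2.0682789328674338;3.2747536133774711
70,8,0.10653531990380175,0.017603648360818624;0.081851270981132984;0.30751236388459802;0.6700075448025018;0.81961200619116426;0.88789865048602223;0.93381357146427035;0.95519800065085292
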