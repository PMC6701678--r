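sex,age,all_cause_rate,disease_attributable_rate
male,16,0.00017431769262468117,4.3579423156170291e-05
male,17,0.00019111578605999715,4.7778946514999288e-05
male,18,0.0002095326247805042,5.238315619512605e-05
male,19,0.00022972419888760411,5.7431049721901028e-05
male,20,0.00025186153044106627,6.2965382610266567e-05
male,21,0.0002761321220110219,6.9033030502755474e-05
male,22,0.00030274154481941249,7.5685386204853123e-05
male,23,0.00033191517992240684,8.2978794980601711e-05
male,24,0.00036390012718155203,9.0975031795388007e-05
male,25,0.00039896729819258875,9.9741824548147187e-05
male,26,0.00043741371089898193,0.00010935342772474548
male,27,0.00047956500532547221,0.00011989125133136805
male,28,0.00052577820173984745,0.00013144455043496186
male,29,0.00057644472460447978,0.00014411118115111995
male,30,0.00063199371793041582,0.00015799842948260395
male,31,0.00069289568011497444,0.00017322392002874361
male,32,0.00075966644904982064,0.00018991661226245516
male,33,0.00083287157125327277,0.00020821789281331819
male,34,0.00091313109203326488,0.00022828277300831622
male,35,0.0010011248072535122,0.00025028120181337806
male,36,0.0010975980211851892,0.0002743995052962973
male,37,0.0012033678592129568,0.00030084196480323919
male,38,0.0013193301888637871,0.00032983254721594677
male,39,0.0014464672077794968,0.00036161680194487421
male,40,0.0015858557629029036,0.00039646394072572589
male,41,0.0017386764713408802,0.00043466911783522004
male,42,0.0019062237201577471,0.00047655593003943677
male,43,0.0020899166297969813,0.00052247915744924533
male,44,0.0022913110739911082,0.00057282776849777706
male,45,0.0025121128579680663,0.00062802821449201658
male,46,0.0027541921665730929,0.00068854804164327323
male,47,0.003019599404681288,0.00075489985117032201
male,48,0.003310582564068743,0.00082764564101718574
male,49,0.0036296062638390809,0.00090740156595977021
male,50,0.0039793726256773512,0.0009948431564193378
male,51,0.0043628441607440251,0.0010907110401860063
male,52,0.0047832688620604528,0.0011958172155151132
male,53,0.0052442077149176232,0.0013110519287294058
male,54,0.0057495648583205054,0.0014373912145801263
male,55,0.0063036206529346753,0.0015759051632336688
male,56,0.0069110679356196927,0.0017277669839049232
male,57,0.007577051767624121,0.0018942629419060302
male,58,0.0083072130131083624,0.0020768032532770906
male,59,0.0091077361171039949,0.0022769340292759987
male,60,0.0099854014875877476,0.0024963503718969369
male,61,0.010947642925344673,0.0027369107313361682
male,62,0.012002610588049823,0.0030006526470124557
male,63,0.013159240021872579,0.0032898100054681448
male,64,0.014427327845299093,0.0036068319613247733
male,65,0.015817614726212952,0.0039544036815532379
male,66,0.01734187635504738,0.0043354690887618449
male,67,0.019013023184549043,0.0047532557961372608
male,68,0.020845209780946571,0.0052113024452366428
male,69,0.022853954712724781,0.0057134886781811953
male,70,0.02505627199245955,0.0062640679981148875
male,71,0.02747081518502148,0.00686770379625537
male,72,0.030118035402741074,0.0075295088506852686
male,73,0.03302035452574998,0.008255088631437495
male,74,0.036202355114669363,0.0090505887786673407
male,75,0.039690988624201014,0.0099227471560502534
male,76,0.0435158036811839,0.010878950920295975
male,77,0.047709196360624935,0.011927299090156234
male,78,0.052306684579535342,0.013076671144883836
male,79,0.057347208932679652,0.014336802233169913
male,80,0.062873462518308748,0.015718365629577187
male,81,0.068932252547490525,0.017233063136872631
female,16,0.00012274346635671616,3.0685866589179039e-05
female,17,0.00013524616169934919,3.3811540424837299e-05
female,18,0.00014902238626085252,3.7255596565213131e-05
female,19,0.00016420186220327752,4.105046555081938e-05
female,20,0.00018092752523656905,4.5231881309142263e-05
female,21,0.00019935687055549079,4.9839217638872698e-05
female,22,0.00021966343587418854,5.4915858968547134e-05
female,23,0.00024203843552320827,6.0509608880802067e-05
female,24,0.00026669256099624725,6.6673140249061812e-05
female,25,0.00029385796490126914,7.3464491225317286e-05
female,26,0.00032379044699762225,8.0947611749405564e-05
female,27,0.00035677186290371412,8.9192965725928529e-05
female,28,0.00039311277815655036,9.827819453913759e-05
female,29,0.00043315539261477008,0.00010828884815369252
female,30,0.00047727676274246603,0.00011931919068561651
female,31,0.00052589235211604002,0.00013147308802901
female,32,0.00057945994358701196,0.00014486498589675299
female,33,0.00063848394993919471,0.00015962098748479868
female,34,0.00070352016363101966,0.00017588004090775492
female,35,0.00077518099034838987,0.00019379524758709747
female,36,0.00085414121564918177,0.00021353530391229544
female,37,0.00094114435900031167,0.00023528608975007792
female,38,0.0010370096750393898,0.00025925241875984745
female,39,0.0011426398679875048,0.00028565996699687619
female,40,0.0012590295918549744,0.00031475739796374359
female,41,0.0013872748164812311,0.00034681870412030778
female,42,0.0015285831476030277,0.00038214578690075692
female,43,0.0016842851981286532,0.00042107129953216331
female,44,0.0018558471176943745,0.00046396177942359363
female,45,0.0020448843984862001,0.00051122109962155001
female,46,0.002253177087327779,0.00056329427183194475
female,47,0.0024826865472772877,0.00062067163681932193
female,48,0.0027355739265668105,0.00068389348164170263
female,49,0.0030142205087947994,0.00075355512719869986
female,50,0.0033212501359967516,0.0008303125339991879
female,51,0.0036595539157382117,0.00091488847893455292
female,52,0.0040323174448815401,0.001008079361220385
female,53,0.0044430508063756907,0.0011107627015939227
female,54,0.0048956216215302528,0.0012239054053825632
female,55,0.0053942914690064195,0.0013485728672516049
female,56,0.0059437560134600461,0.0014859390033650115
female,57,0.0065491892217032117,0.0016372973054258029
female,58,0.0072162920827405991,0.0018040730206851498
female,59,0.0079513462904468937,0.0019878365726117234
female,60,0.0087612733943818535,0.0021903183485954634
female,61,0.0096536999757294052,0.0024134249939323513
female,62,0.010637029462082347,0.0026592573655205868
female,63,0.011720521257307747,0.0029301303143269368
female,64,0.012914377931610118,0.0032285944829025296
female,65,0.014229841292806866,0.0035574603232017164
female,66,0.015679298243459851,0.0039198245608649627
female,67,0.017276397420653931,0.0043190993551634827
female,68,0.019036177716746795,0.0047590444291866988
female,69,0.020975209891290592,0.0052438024728226479
female,70,0.023111752607596559,0.0057779381518991398
female,71,0.025465924363242718,0.0063664810908106795
female,72,0.028059892933487006,0.0070149732333717515
female,73,0.03091808411145756,0.0077295210278643901
female,74,0.034067411710696445,0.0085168529276741112
female,75,0.037537530995848792,0.009384382748962198
female,76,0.041361117927896193,0.010340279481974048
female,77,0.045574176853414403,0.011393544213353601
female,78,0.050216379535173182,0.012554094883793296
female,79,0.055331438716520416,0.013832859679130104
female,80,0.060967519737173202,0.015241879934293301
female,81,0.067177694076348035,0.016794423519087009
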