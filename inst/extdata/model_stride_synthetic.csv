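"t","omega","jerk"
0,0.199603542892349,1.26024557563936e-10
0.01,0.249542952860587,1.34017886172189e-08
0.02,0.303570665950139,9.13798784682758e-07
0.03,0.355358758153427,3.99501688191439e-05
0.04,0.392923237253764,0.00111986814681123
0.05,0.39603585683584,0.0201277576741507
0.06,0.333373440911389,0.231955208368368
0.07,0.1599682437441,1.71393004707302
0.08,-0.184117031884169,8.12011699419676
0.09,-0.772645796112488,24.6667374304313
0.1,-1.68822187502432,48.0442441750095
0.11,-3.01232494444238,60.000000000168
0.12,-4.80997912903325,48.0442441928775
0.13,-7.10995602740582,24.6667386488296
0.14,-9.88308423201393,8.12017026108852
0.15,-13.02292179798,1.7154232046021
0.16,-16.3342385255,0.258792218600569
0.17,-19.5349661598762,0.329401368831975
0.18,-22.2762368030279,2.28635993091084
0.19,-24.1828868047176,10.8268626090978
0.2,-24.9135852132624,32.8889841543738
0.21,-24.235612733823,64.0589922467464
0.22,-22.1038584188125,80.000000000126
0.23,-18.7262638300048,64.0589922333455
0.24,-14.5894611152489,32.8889832406848
0.25,-10.4128194707704,10.8268226991344
0.26,-7.00471759727002,2.2852474118689
0.27,-5.02043827165316,0.309944408728798
0.28,-4.66778138620785,0.0574112120132548
0.29,-5.45897818803321,0.697358782634186
0.3,-6.13396691959436,7.90870131910509
0.31,-4.84809843921867,44.8833987983117
0.32,0.379833607904391,127.196690032258
0.33,11.0890052746673,180.000000000168
0.34,27.8827812415882,127.19669001439
0.35,50.221672787719,44.8833975799133
0.36,76.5874289178598,7.90864805221334
0.37,104.940620130137,0.695865625105105
0.38,133.275908759222,0.0305742017810539
0.39,160.06434470155,0.000670797570974161
0.4,184.455227717281,7.34910487405648e-06
0.41,206.232436743765,4.02053658516568e-08
0.42,225.613556858967,1.09834860196896e-10
0.43,243.008795322753,1.4983145418566e-13
0.44,258.82828635653,1.02063955948629e-16
0.45,273.374175379446,3.47174972633505e-20
0.46,286.809834000427,5.89699870368254e-24
0.47,299.177468431629,5.0017302330752e-28
0.48,310.434924398673,2.11890353418742e-32
0.49,320.492403652996,1.67414252688976e-33
0.5,329.2407325519,4.91200124995948e-31
0.51,336.570124492689,1.17249361757875e-28
0.52,342.381560849072,2.27631437591988e-26
0.53,346.593404846381,3.59437785691281e-24
0.54,349.145222518302,4.61620358830854e-22
0.55,349.99998226572,4.82187461990969e-20
0.56,349.145214444211,4.09653441683158e-18
0.57,346.593369150935,2.83065562993949e-16
0.58,342.381422071931,1.59084256349786e-14
0.59,336.569628068469,7.27171923164127e-13
0.6,329.239087429177,2.70344001035304e-11
0.61,320.487336333981,8.17459239880716e-10
0.62,310.420388956982,2.01041266892693e-08
0.63,299.138594772601,4.02137017665873e-07
0.64,286.712834029669,6.54233273955294e-06
0.65,273.148249325504,8.65687086230913e-05
0.66,258.336985650321,0.000931663293019663
0.67,242.011181488584,0.00815505258666531
0.68,223.722049123109,0.0580582955695921
0.69,202.884099172037,0.336179737142726
0.7,178.922893942394,1.58324643828279
0.71,151.536443452892,6.06450336357056
0.72,121.021361893919,18.8934686782652
0.73,88.5448877475988,47.8737987536658
0.74,56.2055389683781,98.6628864333567
0.75,26.7629657113718,165.378663912344
0.76,3.04196601740159,225.462789661321
0.77,-12.8209069796852,250
0.78,-20.0077854927514,225.462789661321
0.79,-19.2647142617984,165.378663912344
0.8,-12.654767092994,98.6628864333567
0.81,-2.92605369678972,47.8737987536658
0.82,7.24302342800291,18.8934686782652
0.83,15.8408116232538,6.06450336357056
0.84,21.7932453777299,1.58324643828279
0.85,24.9034534974337,0.336179737142726
0.86,25.5795339015018,0.0580582955695921
0.87,24.5077064659644,0.00815505258666531
0.88,22.3897450567238,0.000931663293019663
0.89,19.7935978556815,8.65687086230913e-05
0.9,17.1071304685644,6.54233273955294e-06
0.91,14.5566750405974,4.02137017665873e-07
0.92,12.2514147515124,2.01041266892693e-08
0.93,10.2278629120724,8.17459239880716e-10
0.94,8.48330019949695,2.70344001035304e-11
0.95,6.99680793997603,7.27171923164127e-13
0.96,5.74080916516719,1.59084256349786e-14
0.97,4.68669881799046,2.83065562993949e-16
0.98,3.80729425838155,4.09653441683158e-18
0.99,3.07776036564369,4.82187461990969e-20
1,2.475865243332,4.61620358830854e-22
1.01,1.98195910383066,3.59437785691281e-24
1.02,1.57884092633735,2.27631437591988e-26
1.03,1.25157884543854,1.17249361757875e-28
1.04,0.987311613142765,4.91200124991216e-31
1.05,0.775044217394787,1.67369448506416e-33
1.06,0.605445312792828,4.63835128409804e-36
1.07,0.470651631991977,1.04549226351594e-38
1.08,0.364083018635579,1.91667176566747e-41
1.09,0.280270561983271,2.85788271909032e-44
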