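(((((((((human:0.0065,chimp:0.0068):0.08317458364,mam03:0.07063225681):0.07681264447,(mam04:0.1428411606,mam05:0.1184211199):0.1331810524):0.1397346201,(mam06:0.1063098693,mam07:0.08025896689):0.07161330142):0.009362978024,((((mam08:0.1036071071,((mam09:0.0956214534,mam10:0.01402542228):0.03115712158,mam11:0.07358705386):0.00944997492):0.04677011148,(mam12:0.08737075906,mam13:0.1188206287):0.04027140275):0.08850403851,(((mam14:0.09245539712,mam15:0.1269786482):0.02428205461,((mam16:0.03299799042,mam17:0.1352267759):0.09592244112,mam18:0.04114598554):0.1270071895):0.09721119211,mam19:0.1201671838):0.1129897547):0.1223815221,(((mam20:0.04424542375,mam21:0.03214604226):0.1189736222,mam22:0.1059972427):0.09367274289,((mam23:0.04612886891,mam24:0.09768088229):0.08165165426,mam25:0.1249585238):0.1508240859):0.07244103813):0.06945877065):0.05213722542,(((mam26:0.07428271842,mam27:0.0601657984):0.01799986292,(mam28:0.08813117281,mam29:0.05772632953):0.01795876639):0.03756341771,(((mam30:0.0941540091,mam31:0.01333584065):0.09194905363,(mam32:0.01524916972,mam33:0.1355925426):0.1422027511):0.01828166004,(((mam34:0.07306550387,((mam35:0.02235486363,mam36:0.1024826109):0.05802984678,mam37:0.04019686667):0.1050095871):0.077506211,mam38:0.1013443935):0.09463953242,(mam39:0.1061455018,mam40:0.04169855748):0.09458962737):0.1119545396):0.09387440836):0.03860497113):0.05570026586,(((((sau01:0.0610935463,sau02:0.05484986318):0.06197662504,sau03:0.1010204523):0.04985197914,sau04:0.09995164338):0.1104219722,(sau05:0.03804370214,sau06:0.06871963949):0.05639301499):0.09193672606,((((sau07:0.02584379895,sau08:0.0327175407):0.07587747804,(sau09:0.1056339578,sau10:0.02253899287):0.06551474102):0.1078626431,sau11:0.06490725565):0.06414166953,((sau12:0.1046626941,sau13:0.07993216319):0.1013974938,(sau14:0.04584765586,sau15:0.05101110161):0.09667311662):0.05146592046):0.05784210735):0.0779803722):0.06684031903,(((amp01:0.07717954904,(amp02:0.05027849631,amp03:0.06715190346):0.04457372232):0.05967407065,(amp04:0.1079330911,(amp05:0.09113330778,amp06:0.06438260058):0.1019367596):0.04538003912):0.07520689817,((((amp07:0.1487120262,amp08:0.08464781538):0.09648951275,amp09:0.1442168683):0.06197197741,amp10:0.05796709536):0.06833189764,((amp11:0.06187270343,amp12:0.1079523123):0.06976605882,((amp13:0.1433470487,amp14:0.04180731815):0.09000208578,amp15:0.1261559425):0.08634740452):0.09663666917):0.1371931393):0.1002604785):0.08912042537,(((fsh01:0.213261049,(fsh02:0.2030268253,fsh03:0.08849805259):0.05856513564):0.2162729208,(fsh04:0.05986399915,((fsh05:0.04828363683,fsh06:0.1770317921):0.09402954138,fsh07:0.1851475019):0.1259732932):0.06488283226):0.05856166879,((((fsh08:0.1739347391,fsh09:0.1244040686):0.2221824933,((((fsh10:0.06003214636,fsh11:0.06197510313):0.1666236391,fsh12:0.1446583589):0.1140767262,fsh13:0.04745652825):0.1915358368,fsh14:0.1337863565):0.05116548031):0.06023812398,fsh15:0.05668566144):0.1759568856,((((((fsh16:0.07853609339,fsh17:0.1666325003):0.1987524864,fsh18:0.1717082446):0.208680564,fsh19:0.1047092229):0.1923734875,(((fsh20:0.09533106909,(fsh21:0.06986452771,(fsh22:0.07444541015,fsh23:0.1150660945):0.07166720093):0.219884588):0.1775788195,fsh24:0.1854041192):0.1889017336,fsh25:0.1390869159):0.1621990877):0.1257446508,(fsh26:0.1143569308,fsh27:0.1743886743):0.1704055385):0.2005027021,((fsh28:0.08827478043,fsh29:0.1820484984):0.1526964797,fsh30:0.06684201173):0.1277482278):0.142238913):0.0981398291):0.1114005317); 
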