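((((human:0.0065,chimp:0.0068):0.1649127474,((sup03:0.1027547467,((sup04:0.05518300109,sup05:0.01658001711):0.1449957594,(sup06:0.1204062146,(sup07:0.1224249173,sup08:0.1374470719):0.1678301475):0.04605250517):0.1485610752):0.1641361163,(sup09:0.171789457,sup10:0.0104226166):0.1374529625):0.04762491476):0.1552236919,(((((sup11:0.117653216,sup12:0.1604972569):0.01177308356,sup13:0.127408888):0.03104678867,sup14:0.03908600453):0.07974333849,sup15:0.0485623433):0.06231107118,(sup16:0.07275316089,(sup17:0.02016694781,sup18:0.01905598384):0.0473189393):0.1475089749):0.1667774359):0.05239320085,((((((lau01:0.01538197755,((lau02:0.03806081426,lau03:0.1691390548):0.04685602721,lau04:0.09622960906):0.03461287772):0.1151249221,(lau05:0.1205357395,lau06:0.08449947603):0.1289727533):0.1241788834,(lau07:0.1244264559,lau08:0.04721899438):0.1134216397):0.1057543524,(lau09:0.1041503227,(lau10:0.03082034858,((lau11:0.03049686245,(lau12:0.10817539,lau13:0.01848391427):0.1115402936):0.09846027456,lau14:0.05084901346):0.1693441376):0.1132438225):0.1516460588):0.04112636351,(lau15:0.03941286065,lau16:0.1465475288):0.03899912137):0.03139030153,(lau17:0.08533430214,lau18:0.09298744824):0.1559319603):0.06549150106); 
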