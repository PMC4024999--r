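timestamp,wind_speed,wind_direction,temperature,rel_humidity,precipitation,obukhov_length,roughness_length
2009-05-01T00:00:00,1.7590255823469523,270,17.57866922574198,50.82902958159033,0,40,0.1
2009-05-01T01:00:00,1.519428784386449,263.38971845660717,17.157017685464606,65.37454260848627,0,40,0.1
2009-05-01T02:00:00,1.506566645896487,284.0254419562671,14.964530894410995,68.52161162481968,0,40,0.1
2009-05-01T03:00:00,1.5108135616587615,272.666109041572,13.546916019288549,50.59137138396407,0,40,0.1
2009-05-01T04:00:00,1.5346921770197157,271.6299945071869,11.7512096240397,51.62326458584798,0,40,0.1
2009-05-01T05:00:00,2.010451618338866,272.4612768721467,11.455695078835276,64.75734282992056,0,40,0.1
2009-05-01T06:00:00,1.9698584107517667,275.8265771968869,7.924328335293144,59.418536056998654,0,1000000,0.1
2009-05-01T07:00:00,2.090662578547845,262.9998287700428,8.680065767508342,71.54729284303696,0,1000000,0.1
2009-05-01T08:00:00,2.5129032691832984,262.58494839124126,10.897888955622467,71.38196467996879,0,-60,0.1
2009-05-01T09:00:00,2.5164174660239262,256.0020686864783,9.35874412848732,58.97771707123375,0,-60,0.1
2009-05-01T10:00:00,2.5148943090893123,259.0321710713133,9.922537458348435,60.67547562598056,0,-15,0.1
2009-05-01T11:00:00,3.414214080505233,262.2776827224084,10.916387518631074,73.51814235176354,0,-15,0.1
2009-05-01T12:00:00,3.075492708065882,243.02588442323233,11.5017201060731,66.51661071931932,0,-15,0.1
2009-05-01T13:00:00,2.9823790150018183,244.99414612701324,14.262587519504562,60.7787765426901,0,-15,0.1
2009-05-01T14:00:00,3.2841702522409593,245.9609279784625,15.336415078990495,74.54348178098971,0,-15,0.1
2009-05-01T15:00:00,3.777042806308466,241.8480313078203,15.175969176722209,63.15694778286392,0,-15,0.1
2009-05-01T16:00:00,3.6356345186428745,259.2823428805352,18.570878017671255,54.18883878959442,0,-60,0.1
2009-05-01T17:00:00,3.3484346042013042,249.87065265361036,19.493053796773292,57.8164548384139,0,-60,0.1
2009-05-01T18:00:00,3.254454872743642,259.6614299782667,20.531609998047703,66.33241019824877,0,1000000,0.1
2009-05-01T19:00:00,2.8842387553759927,264.91670522949573,21.71963909701148,73.19624109973458,0,1000000,0.1
2009-05-01T20:00:00,2.583153416070963,266.40187865650836,21.71612004898229,73.08006628880008,0,40,0.1
2009-05-01T21:00:00,2.69841486518096,270.0984760797318,21.4876481481172,74.80052778332872,0,40,0.1
2009-05-01T22:00:00,2.014518949749599,267.8082118980566,20.04116808794545,52.849101401085846,0,40,0.1
2009-05-01T23:00:00,2.142429995744305,271.15685753775625,17.638777691787062,66.56709933658779,0,40,0.1
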