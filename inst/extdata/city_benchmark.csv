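city,country,region,income_group,pct_access_food,pct_access_convenience,pct_access_pt_any,pct_access_pt_30min,pct_access_pt_20min,pct_access_pos_any,pct_access_pos_large,pm25_transport,pct_scenarioA_pop,pct_scenarioB_pop,pct_scenarioA_int,pct_scenarioB_int
Maiduguri,Nigeria,Africa,middle,17.4,27.4,9.6,NA,NA,1.9,0.5,7.5,98.0,95.9,45.6,28.5
Mexico City,Mexico,North America,middle,26.4,22.7,35.8,24.7,19.7,49.6,19.7,532.0,98.9,98.1,89.6,78.6
Baltimore,USA,North America,high,14.3,29.1,63.1,51.3,42.8,62.5,39.2,324.8,39.6,28.0,64.8,51.7
Phoenix,USA,North America,high,5.6,21.0,66.0,61.6,24.1,36.5,24.6,268.3,30.1,15.7,74.4,51.0
Seattle,USA,North America,high,15.5,26.1,60.3,36.3,26.6,59.2,35.0,316.3,10.9,6.4,61.3,43.2
Sao Paulo,Brazil,South America,middle,35.2,36.7,96.1,95.7,94.2,71.7,15.5,2306.5,99.6,99.4,88.0,70.4
Hong Kong,Hong Kong,Asia,high,48.9,52.2,89.5,86.9,83.6,86.9,54.1,1903.7,98.3,97.7,95.7,91.5
Chennai,India,Asia,middle,19.7,15.6,39.1,3.2,3.2,41.1,11.3,657.9,99.8,99.7,90.4,79.3
Bangkok,Thailand,Asia,middle,15.3,33.4,63.0,62.1,43.2,14.1,6.5,4163.9,98.2,97.0,61.5,39.7
Hanoi,Vietnam,Asia,middle,38.0,46.4,65.5,21.9,11.2,26.7,14.1,2062.8,95.7,93.0,67.6,56.3
Adelaide,Australia,Australasia,high,18.8,19.9,89.2,81.9,53.7,87.3,58.0,147.4,3.7,0.0,38.4,12.6
Melbourne,Australia,Australasia,high,20.7,29.6,86.7,67.2,49.4,88.2,63.3,1364.0,33.4,17.8,37.8,20.8
Sydney,Australia,Australasia,high,22.3,28.7,94.7,78.4,57.7,90.1,60.3,564.8,67.5,51.0,24.9,13.4
Auckland,New Zealand,Australasia,high,31.2,47.9,91.0,81.4,55.7,90.6,64.9,340.3,47.9,22.3,26.6,14.5
Graz,Austria,Europe,high,62.6,56.4,92.2,NA,NA,84.9,39.5,14.4,64.0,44.1,92.5,81.3
Ghent,Belgium,Europe,high,49.5,44.1,86.5,NA,NA,92.7,62.7,47.4,0.0,0.0,67.5,54.8
Olomouc,Czech Republic,Europe,high,37.2,43.7,88.8,NA,NA,90.4,46.0,2.6,0.0,0.0,69.0,54.2
Odense,Denmark,Europe,high,43.7,36.1,84.4,66.1,59.0,92.9,73.4,3.9,6.0,0.0,94.8,85.3
Cologne,Germany,Europe,high,51.1,56.9,79.0,71.7,60.2,89.6,65.8,158.9,47.5,21.6,83.9,71.6
Lisbon,Portugal,Europe,high,64.2,60.7,97.0,95.7,92.8,90.1,51.3,208.1,98.1,96.8,99.7,98.6
Barcelona,Spain,Europe,high,63.8,61.6,91.4,78.3,75.8,88.2,62.8,186.1,95.5,92.3,82.6,74.9
Valencia,Spain,Europe,high,59.7,48.4,81.6,78.3,77.2,78.4,43.8,105.0,97.8,95.8,78.6,72.3
Vic,Spain,Europe,high,50.7,40.1,57.7,NA,NA,81.4,74.8,NA,47.1,24.3,65.3,56.4
Bern,Switzerland,Europe,high,69.3,73.5,94.8,93.6,91.8,98.9,80.0,10.3,82.1,58.3,99.3,98.2
Belfast,UK,Europe,high,29.0,47.8,92.9,82.9,72.6,65.0,46.8,29.4,59.6,40.1,91.1,74.0
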