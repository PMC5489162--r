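occurrenceID,scientificName,genus,family,decimalLatitude,decimalLongitude,coordinateUncertaintyInMeters,geodeticDatum,country,locality,eventDate
occ-1,Tetragonisca angustula,Tetragonisca,Apidae,-22.9056,-47.0608,100,WGS84,Brazil,"Campinas, SP",2019-03-12
occ-2,Tetragonisca angustula,,,-35.3848,13.8352,100,SIRGAS2000,Brazil,,2018-11-02
occ-3,Apis mellifera,Apis,Apidae,,,,WGS84,Brazil,"Campinas, SP",2020-01-15
occ-4,Tetragonisca angustvla,Tetragonisca,Apidae,-15.8000,-47.9000,50,WGS84,Brazil,"Brasilia, DF",2017-06-28
occ-5,Mimosa pudica,Mimosa,Fabaceae,91.5000,-47.9000,50,WGS84,Brazil,"Brasilia, DF",2021-09-09
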