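"id","starting_age_years","total_training_years","currently_training","hours_per_week","n_instruments_lifetime","percent_correct","kernel_scale","latency_shift_ms"
"S01",4,13.7,TRUE,14.7,1,83.3333333333333,0.877973146504047,2
"S02",5,19,TRUE,23.7,3,70,0.959372217323591,0
"S03",5,10.6,TRUE,5.9,3,76.6666666666667,0.924445125404067,-1
"S04",4,13.8,TRUE,19.5,2,76.6666666666667,0.938006337399114,0
"S05",5,19.9,TRUE,10.1,3,80,0.945706832106999,0
"S06",4,12.1,TRUE,16.6,1,70,1.10388708688669,2
"S07",4,13.9,TRUE,1.3,1,83.3333333333333,0.965155455867779,0
"S08",4,13.4,TRUE,12.6,2,86.6666666666667,0.903759953131561,0
"S09",4,11.9,TRUE,20.9,1,70,1.30814194139582,0
"S10",7,11.1,TRUE,18.4,2,80,0.957991971324866,0
"S11",5,16.5,TRUE,19.8,4,70,0.964725855075286,0
"S12",7,17.9,TRUE,1.6,4,86.6666666666667,0.980161281163086,1
"S13",4,16.9,TRUE,12.5,1,76.6666666666667,1.153191437093,2
"S14",7,12.4,TRUE,2.7,3,76.6666666666667,0.985394824739113,1
"S15",7,15.2,TRUE,16.9,3,66.6666666666667,0.992501421387444,1
"S16",6,12.9,TRUE,12,4,80,0.87255281328559,-1
"S17",7,12.6,TRUE,12.5,1,76.6666666666667,0.937204234184726,1
"S18",5,18.8,TRUE,9.1,2,83.3333333333333,1.01210476485068,0
"S19",NA,0,FALSE,0,0,90,0.888892567478235,-1
"S20",NA,0,FALSE,0,0,70,1.11215462622989,1
"S21",NA,0,FALSE,0,0,83.3333333333333,0.738097893353986,0
"S22",13,1.5,FALSE,0,1,80,1.06323013549256,1
"S23",13,2.3,FALSE,0,1,90,0.735437319119516,-1
"S24",NA,0,FALSE,0,0,73.3333333333333,0.94158069520279,0
"S25",11,2.3,FALSE,0,2,83.3333333333333,0.89973412057294,-1
"S26",NA,0,FALSE,0,0,73.3333333333333,0.877727624504366,0
"S27",NA,0,FALSE,0,0,83.3333333333333,0.98868514440922,0
"S28",NA,0,FALSE,0,0,86.6666666666667,0.681900255248533,-1
"S29",NA,0,FALSE,0,0,80,1.26530938121018,1
"S30",11,2.4,FALSE,0,1,83.3333333333333,0.716774145546925,-1
"S31",NA,0,FALSE,0,0,86.6666666666667,0.911461357383732,-1
"S32",NA,0,FALSE,0,0,80,0.799967624899622,1
"S33",12,2.1,FALSE,0,2,80,0.860567003799067,-1
"S34",NA,0,FALSE,0,0,86.6666666666667,1.51806015976315,0
"S35",12,1,FALSE,0,1,83.3333333333333,1.00348518311518,0
"S36",NA,0,FALSE,0,0,76.6666666666667,0.773167082144574,0
"S37",8,2.9,FALSE,0,1,66.6666666666667,0.720275784067366,2
"S38",NA,0,FALSE,0,0,90,1.09421522875149,2
"S39",NA,0,FALSE,0,0,73.3333333333333,0.996294914288442,0
"S40",NA,0,FALSE,0,0,66.6666666666667,0.938367444404015,-2
"S41",NA,0,FALSE,0,0,73.3333333333333,0.83037952016359,2
"S42",10,1.6,FALSE,0,2,83.3333333333333,0.742678478558131,1
"S43",15,1.7,FALSE,0,1,76.6666666666667,0.806510421735934,1
"S44",12,11.7,TRUE,3.1,1,66.6666666666667,1.22140979436756,0
"S45",10,10.3,TRUE,6.8,2,66.6666666666667,0.883156074698681,1
"S46",7,12.6,FALSE,0,1,83.3333333333333,0.758141398274719,0
"S47",12,13.6,TRUE,2.6,1,83.3333333333333,1.45333094375283,0
"S48",9,14.5,TRUE,4,1,86.6666666666667,1.08873892342949,0
"S49",5,12.6,FALSE,0,2,83.3333333333333,0.953391720737811,-1
"S50",4,12.2,FALSE,0,2,80,1.23577290673775,1
"S51",6,10.3,FALSE,0,3,70,1.19397076563156,2
"S52",10,16.7,TRUE,8.7,1,80,0.883513586192995,0
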