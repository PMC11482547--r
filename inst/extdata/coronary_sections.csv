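"subject","section","eye_percent","digital_percent","subject_sex","subject_age","cause_of_death","atherosclerosis_class"
"A",1,55,65.6,"m",51,"Burns, sepsis, DIC","Fibrosis plaque (uncomplicated atherosclerosis)"
"A",2,50,60,"m",51,"Burns, sepsis, DIC","Fibrosis plaque (uncomplicated atherosclerosis)"
"A",3,55,65,"m",51,"Burns, sepsis, DIC","Fibrosis plaque (uncomplicated atherosclerosis)"
"A",4,85,83,"m",51,"Burns, sepsis, DIC","Fibrosis plaque (uncomplicated atherosclerosis)"
"B",5,35,41.6,"f",83,"Hypothermia","Initial atherosclerosis"
"B",6,35,35.2,"f",83,"Hypothermia","Initial atherosclerosis"
"C",7,50,54,"f",64,"Subarachnoid haemorrhage","Fibrosis plaque (uncomplicated atherosclerosis)"
"C",8,30,37.6,"f",64,"Subarachnoid haemorrhage","Fibrosis plaque (uncomplicated atherosclerosis)"
"C",9,40,42.1,"f",64,"Subarachnoid haemorrhage","Fibrosis plaque (uncomplicated atherosclerosis)"
"D",10,75,77.8,"m",62,"SCD due to arrhythmia","Fibrosis plaque (uncomplicated atherosclerosis)"
"D",11,80,84.1,"m",62,"SCD due to arrhythmia","Fibrosis plaque (uncomplicated atherosclerosis)"
"D",12,65,57.8,"m",62,"SCD due to arrhythmia","Fibrosis plaque (uncomplicated atherosclerosis)"
"D",13,85,82.2,"m",62,"SCD due to arrhythmia","Fibrosis plaque (uncomplicated atherosclerosis)"
"D",14,80,83.6,"m",62,"SCD due to arrhythmia","Fibrosis plaque (uncomplicated atherosclerosis)"
"D",15,70,76.7,"m",62,"SCD due to arrhythmia","Fibrosis plaque (uncomplicated atherosclerosis)"
"D",16,50,54,"m",62,"SCD due to arrhythmia","Fibrosis plaque (uncomplicated atherosclerosis)"
"E",17,90,91,"m",59,"SCD due to arrhythmia","Complicated atherosclerosis"
"E",18,85,91.6,"m",59,"SCD due to arrhythmia","Complicated atherosclerosis"
"E",19,80,79.6,"m",59,"SCD due to arrhythmia","Complicated atherosclerosis"
"E",20,95,91.6,"m",59,"SCD due to arrhythmia","Complicated atherosclerosis"
"E",21,40,53.4,"m",59,"SCD due to arrhythmia","Complicated atherosclerosis"
"F",22,65,71.4,"f",76,"SCD due to arrhythmia","Fibrosis plaque (uncomplicated atherosclerosis)"
"G",23,45,53,"m",77,"Polytrauma, DIC","Complicated atherosclerosis"
"G",24,47,55.5,"m",77,"Polytrauma, DIC","Complicated atherosclerosis"
"H",25,92,85.7,"m",29,"Myocardial infarction","Complicated atherosclerosis"
"H",26,80,81.8,"m",29,"Myocardial infarction","Complicated atherosclerosis"
"H",27,82,76.1,"m",29,"Myocardial infarction","Complicated atherosclerosis"
"H",28,83,66.4,"m",29,"Myocardial infarction","Complicated atherosclerosis"
"H",29,77,75.9,"m",29,"Myocardial infarction","Complicated atherosclerosis"
"H",30,55,73.3,"m",29,"Myocardial infarction","Complicated atherosclerosis"
"H",31,75,71.7,"m",29,"Myocardial infarction","Complicated atherosclerosis"
"I",32,65,64.2,"m",76,"Polytrauma, DIC","Fibrosis plaque (uncomplicated atherosclerosis)"
"I",33,92,82,"m",76,"Polytrauma, DIC","Fibrosis plaque (uncomplicated atherosclerosis)"
"I",34,62,62.6,"m",76,"Polytrauma, DIC","Fibrosis plaque (uncomplicated atherosclerosis)"
"I",35,62,62.7,"m",76,"Polytrauma, DIC","Fibrosis plaque (uncomplicated atherosclerosis)"
"I",36,90,87.1,"m",76,"Polytrauma, DIC","Fibrosis plaque (uncomplicated atherosclerosis)"
"I",37,82,71,"m",76,"Polytrauma, DIC","Fibrosis plaque (uncomplicated atherosclerosis)"
"I",38,88,82.8,"m",76,"Polytrauma, DIC","Fibrosis plaque (uncomplicated atherosclerosis)"
"I",39,78,68.3,"m",76,"Polytrauma, DIC","Fibrosis plaque (uncomplicated atherosclerosis)"
"J",40,70,66,"m",53,"SCD due to arrhythmia","Fibrosis plaque (uncomplicated atherosclerosis)"
"J",41,70,73.1,"m",53,"SCD due to arrhythmia","Fibrosis plaque (uncomplicated atherosclerosis)"
"J",42,80,78.6,"m",53,"SCD due to arrhythmia","Fibrosis plaque (uncomplicated atherosclerosis)"
"J",43,80,76.5,"m",53,"SCD due to arrhythmia","Fibrosis plaque (uncomplicated atherosclerosis)"
"J",44,75,71.8,"m",53,"SCD due to arrhythmia","Fibrosis plaque (uncomplicated atherosclerosis)"
"K",45,99,99,"m",56,"Myocardial infarction","Complicated atherosclerosis"
"K",46,98,96.9,"m",56,"Myocardial infarction","Complicated atherosclerosis"
"K",47,98,98.6,"m",56,"Myocardial infarction","Complicated atherosclerosis"
"K",48,90,94.5,"m",56,"Myocardial infarction","Complicated atherosclerosis"
"K",49,65,73.5,"m",56,"Myocardial infarction","Complicated atherosclerosis"
"K",50,65,67.7,"m",56,"Myocardial infarction","Complicated atherosclerosis"
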