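name,abbreviation,cmax_uM,dili_concern,severity,hepatotox_class,is_control
Acarbose,ACA,0.15,most,severe,8,FALSE
Acetaminophen,APAP,139,most,severe,5,FALSE
Adefovir,ADV,0.085,less,non_severe,2,FALSE
Allopurinol,ALLO,13.81,most,severe,8,FALSE
Altretamine,ALM,3.76,ambiguous,non_severe,2,FALSE
Amiodarone,AMIO,0.807,most,severe,8,FALSE
Amoxicillin,AX,22.3,less,non_severe,5,FALSE
Azathioprine,AZA,0.34,most,severe,5,FALSE
Benzbromarone,BB,4.339,most,severe,8,FALSE
Betaine,BET,940,no,non_severe,1,FALSE
Bicalutamide,BAT,1.97,most,severe,8,FALSE
Bosentan,BOS,7.4,most,severe,7,FALSE
Bromfenac,BFC,17.96,most,severe,8,FALSE
Buspirone,BUS,0.016,ambiguous,non_severe,3,FALSE
Busulfan,BU,0.277,most,severe,8,FALSE
Captopril,CPL,8.882,less,non_severe,7,FALSE
Carbamazepine,CBZ,50.79,most,severe,7,FALSE
Chloramphenicol,CAMP,46.36,no,non_severe,1,FALSE
Chlormezanone,CMZ,10.59,most,severe,8,FALSE
Chlorpromazine,CPZ,0.94,less,non_severe,2,FALSE
Chlorpropamide,CHL,130.1,less,non_severe,2,FALSE
Cimetidine,CMT,11.89,less,non_severe,2,FALSE
Ciprofloxacin,CIPX,6.58,most,severe,7,FALSE
Clofibrate,CLO,470,less,non_severe,3,FALSE
Clotrimazole,CTZ,0.087,less,non_severe,3,FALSE
Clozapine,CLZ,2.44,most,severe,5,FALSE
Colchicine,CLC,0.016,ambiguous,non_severe,6,FALSE
Cyclosporin A,CSA,0.2,most,severe,NA,FALSE
Dacarbazine,DTIC,20.64,most,severe,6,FALSE
Danazol,DNZ,0.109,most,severe,8,FALSE
Dantrolene,DAN,7.9,most,severe,8,FALSE
Dexamethasone,DXS,0.224,ambiguous,non_severe,3,FALSE
Dextromethorphan hbr,DXM,0.022,no,non_severe,NA,FALSE
Diclofenac,DCF,10.1,most,severe,8,FALSE
Didanosine,DDL,9.83,most,severe,8,FALSE
Diethylmaleate,DEM,NA,control,control,NA,TRUE
Digoxin,DIG,0.003,no,non_severe,1,FALSE
Diltiazem,DTZ,0.356,most,severe,4,FALSE
Disulfiram,DIS,5.4,most,severe,8,FALSE
Dmso,DMSO,NA,control,control,NA,TRUE
Edrophonium,EDR,60.2,no,non_severe,1,FALSE
Enalapril,ENP,0.4,less,non_severe,7,FALSE
Entacapone,ECP,3.93,less,non_severe,1,FALSE
Epinephrine,EPI,0.002,no,non_severe,1,FALSE
Erythromycin,ERYC,11,most,severe,5,FALSE
Ethambutol,EMB,24.47,most,severe,8,FALSE
Etodolac,ELAC,68.49,most,severe,8,FALSE
Etoposide,ETO,NA,control,control,NA,TRUE
Famotidine,FAM,0.308,less,non_severe,3,FALSE
Fenofibrate,FF,4.1,less,non_severe,3,FALSE
Fenoprofen,FPF,58.2,most,severe,8,FALSE
Fialuridine,FIAU,1,most,severe,8,FALSE
Fluoxetine,FLX,0.05,less,non_severe,3,FALSE
Flurbiprofen,FBP,57.32,ambiguous,non_severe,3,FALSE
Folic acid,FA,0.043,no,non_severe,1,FALSE
Furosemide,FUR,3.29,ambiguous,non_severe,2,FALSE
Ganciclovir,GCV,4.62,ambiguous,non_severe,7,FALSE
Glimepiride,GLP,1.12,less,non_severe,7,FALSE
Griseofulvin,GF,4.54,most,severe,8,FALSE
Haloperidol,HDL,0.005,less,non_severe,5,FALSE
Hydroxyzine,HYZ,0.27,no,non_severe,1,FALSE
Imipramine,IM,0.29,less,non_severe,3,FALSE
Indomethacin,IMN,5.59,most,severe,8,FALSE
Isoniazid,INH,76.56,most,severe,8,FALSE
Isoproterenol,IPR,2.02,no,non_severe,1,FALSE
Kanamycin,KM,60.1,no,non_severe,1,FALSE
Ketoconazole,KTZ,6.59,most,severe,8,FALSE
Ketorolac,KTL,3.53,less,non_severe,3,FALSE
Labetalol,LABE,2.68,most,severe,8,FALSE
Maprotiline,MPT,0.18,ambiguous,non_severe,5,FALSE
Mebendazole,MBZ,0.13,less,non_severe,3,FALSE
Meclizine,MCZ,0.026,no,non_severe,1,FALSE
Mercaptopurine,MP,0.486,most,severe,8,FALSE
Metformin,MF,7.78,less,non_severe,1,FALSE
Methimazole,MTZ,2.62,most,severe,8,FALSE
Methotrexate,MTX,0.77,most,severe,3,FALSE
Methyldopa,MD,18.94,most,severe,8,FALSE
Metoprolol,MTPL,0.56,less,non_severe,5,FALSE
Mexiletine,MXT,3.83,most,severe,3,FALSE
Moxisylyte,MOX,0.16,most,severe,8,FALSE
Naproxen,NPX,0.2,less,non_severe,3,FALSE
Nefazodone,NFZ,3.95,most,severe,8,FALSE
Neomycin,NEO,0.44,no,non_severe,1,FALSE
Nifedipine,NFP,0.43,less,non_severe,3,FALSE
Nimesulide,NMS,21.082,most,severe,8,FALSE
Nitrofurantoin,NTF,6,most,severe,8,FALSE
Nizatidine,NIZ,4,less,non_severe,5,FALSE
Ofloxacin,OFX,9.96,less,non_severe,3,FALSE
Omeprazole,OMZ,4.7,less,non_severe,4,FALSE
Oxytetracycline,OTC,3.26,ambiguous,non_severe,2,FALSE
Paroxetine,PXT,0.061,less,non_severe,8,FALSE
Perhexiline,PHX,2.16,most,severe,8,FALSE
Phenobarbital,PBT,145.5,less,non_severe,3,FALSE
Phenytoin,PT,21.72,most,severe,8,FALSE
Pioglitazone,PGZ,2.946,less,non_severe,3,FALSE
Prednisolone,PRD,0.68,less,non_severe,3,FALSE
Primaquine,PQ,0.615,no,non_severe,1,FALSE
Primidone,PRI,4.67,no,non_severe,1,FALSE
Procyclidine,PCD,0.404,no,non_severe,1,FALSE
Propranolol,PPL,0.201,ambiguous,non_severe,3,FALSE
Propylthiouracil,PTU,9.1,most,severe,8,FALSE
Ranitidine,RNT,1.79,less,non_severe,5,FALSE
Ribavirin,RBV,2.61,ambiguous,non_severe,7,FALSE
Rifampicin,RFP,15,most,severe,NA,FALSE
Simvastatin,SVN,0.082,less,non_severe,3,FALSE
Succinylcholine,SUCC,137.74,no,non_severe,1,FALSE
Sulindac,SUL,31.985,most,severe,8,FALSE
Tacrolimus,TAC,0.037,less,non_severe,5,FALSE
Tamoxifen,TMX,0.162,most,severe,8,FALSE
Terbinafine,TRB,4,most,severe,8,FALSE
Thapsigargin,TG,NA,control,control,NA,TRUE
Thioridazine,TDZ,0.55,less,non_severe,5,FALSE
Ticlopidine,TPD,8.075,most,severe,4,FALSE
Tnfa,TNF,NA,control,control,NA,TRUE
Tolbutamide,TOLB,233.03,ambiguous,non_severe,2,FALSE
Tolcapone,TC,21.99,most,severe,8,FALSE
Trazodone,TZ,5.056,less,non_severe,5,FALSE
Troglitazone,TRG,6.39,most,severe,8,FALSE
Verapamil,VRP,0.5,less,non_severe,3,FALSE
Warfarin,WAR,4.86,less,non_severe,5,FALSE
Ximelagatran,XML,0.3,most,severe,8,FALSE
Zafirlukast,ZFL,1.21,most,severe,8,FALSE
Zimelidine,ZMI,0.267,most,severe,8,FALSE
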