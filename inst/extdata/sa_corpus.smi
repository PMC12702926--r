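CC(=O)Oc1ccccc1C(=O)O aspirin
CC(C)Cc1ccc(cc1)C(C)C(=O)O ibuprofen
CC(=O)Nc1ccc(O)cc1 paracetamol
Cn1cnc2c1c(=O)n(C)c(=O)n2C caffeine
CN1C2CCC1CC(C2)OC(=O)C(CO)c1ccccc1 atropine_core
CC(N)Cc1ccccc1 amphetamine
CNC(C)Cc1ccccc1 methamphetamine
NC(=O)c1ccc(N)cc1 aminobenzamide
Clc1ccccc1C(=O)N chlorobenzamide
OC(=O)c1ccccc1O salicylic_acid
COc1ccc(CCN)cc1 methoxyphenethylamine
CCOC(=O)c1ccccc1 ethyl_benzoate
CC(=O)OCC acetate_ester
CCN(CC)CC triethylamine
CCOCC diethyl_ether
CCO ethanol
CCCO propanol
CC(C)O isopropanol
CC(C)(C)O tbutanol
OCCO glycol
OCC(O)CO glycerol
CC(=O)C acetone
CCC(=O)C butanone
CC(=O)N acetamide
CC(=O)NC n_methylacetamide
CCNC(=O)C ethylacetamide
CC(=O)OC methyl_acetate
CCOC(=O)C ethyl_acetate
C1CCCCC1 cyclohexane
C1CCCC1 cyclopentane
C1CCNCC1 piperidine
C1CCOC1 thf
C1COCCN1 morpholine_core
O1CCOCC1 dioxane
C1CCNC1 pyrrolidine
C1CN(C)CCN1C dimethylpiperazine
c1ccccc1 benzene
Cc1ccccc1 toluene
Cc1ccccc1C xylene
COc1ccccc1 anisole
Oc1ccccc1 phenol
Nc1ccccc1 aniline
Clc1ccccc1 chlorobenzene
Fc1ccccc1 fluorobenzene
Brc1ccccc1 bromobenzene
c1ccncc1 pyridine
c1ccnc(N)c1 aminopyridine
Cc1ccncc1 picoline
c1cnc2ccccc2c1 quinoline_iso
c1ccc2ccccc2c1 naphthalene
c1ccc2[nH]ccc2c1 indole
c1ccc2occc2c1 benzofuran
c1ccc2sccc2c1 benzothiophene
c1ccoc1 furan
c1ccsc1 thiophene
c1cc[nH]c1 pyrrole
c1cnc[nH]1 imidazole
c1cc[nH]n1 pyrazole
c1cncnc1 pyrimidine
Nc1ncccn1 aminopyrimidine
Nc1nc(N)ccn1 diaminopyrimidine
c1cnccn1 pyrazine
c1ccnnc1 pyridazine
c1nnc[nH]1 triazole
c1ocnc1 oxazole
c1scnc1 thiazole
Cc1nccs1 methylthiazole
CC(C)C isobutane
CCCC butane
CCCCCC hexane
CCCCCCCC octane
CC(C)CC(C)C dimethylpentane
C=C ethylene
CC=CC butene
C#N hydrogen_cyanide_c
CC#N acetonitrile
CCC#N propionitrile
CS(=O)C dmso
CS(=O)(=O)C methylsulfone
CS(=O)(=O)N sulfonamide_s
NS(=O)(=O)c1ccccc1 benzenesulfonamide
O=S(=O)(N)c1ccc(N)cc1 sulfanilamide
CNC methylamine_dimethyl
CN(C)C trimethylamine
NCCN ethylenediamine
NCCO ethanolamine
OCCN(C)C dimethylaminoethanol
CC(N)C(=O)O alanine
NCC(=O)O glycine
CC(C)C(N)C(=O)O valine
N[C@@H](Cc1ccccc1)C(=O)O phenylalanine
OC(=O)CC(=O)O malonic_acid
OC(=O)CCC(=O)O succinic_acid
CC(O)C(=O)O lactic_acid
OC(=O)C=CC(=O)O fumaric_acid
OC(=O)c1ccccc1 benzoic_acid
OC(=O)c1ccncc1 isonicotinic_acid
NC(=O)c1ccncc1 isonicotinamide
CNC(=O)c1ccccc1 n_methylbenzamide
CC(=O)Nc1ccccc1 acetanilide
O=C1CCCCC1 cyclohexanone
O=C1CCCC1 cyclopentanone
O=C1CCCN1 pyrrolidinone
CN1CCCC1=O n_methylpyrrolidinone
O=C1NC(=O)NC(=O)C1 barbituric_acid
Cn1ccnc1 methylimidazole
CCn1ccnc1 ethylimidazole
c1ccc(cc1)c1ccccc1 biphenyl
c1ccc(cc1)Cc1ccccc1 diphenylmethane
c1ccc(cc1)Oc1ccccc1 diphenylether
c1ccc(cc1)Nc1ccccc1 diphenylamine
c1ccc(cc1)C(=O)c1ccccc1 benzophenone
CC(C)(C)c1ccc(O)cc1 tbutylphenol
COc1ccc(C=O)cc1 anisaldehyde
COc1cc(C=CC(=O)O)ccc1O ferulic_acid
Oc1ccc(C=CC(=O)O)cc1 coumaric_acid
COc1ccc(CCN(C)C)cc1 methoxyphenethyl_dimethylamine
Clc1ccc(Cl)cc1 dichlorobenzene
Clc1ccc(cc1)C(=O)O chlorobenzoic_acid
Fc1ccc(cc1)C(=O)O fluorobenzoic_acid
FC(F)(F)c1ccccc1 trifluoromethylbenzene
FC(F)(F)c1cccc(N)c1 trifluoromethylaniline
CC(C)NCC(O)COc1ccccc1 propranolol_fragment
CNCC(O)c1ccc(O)c(O)c1 adrenaline
NCC(O)c1ccc(O)c(O)c1 noradrenaline
NCCc1ccc(O)c(O)c1 dopamine
NCCc1c[nH]c2ccccc12 tryptamine
CNCCc1c[nH]c2ccccc12 methyltryptamine
NCCc1c[nH]cn1 histamine
OCC1OC(O)C(O)C(O)C1O glucose
OCC1OC(CO)(O)C(O)C1O fructose_core
CC1CCC(C(C)C)C(O)C1 menthol_core
CC1=CCC(CC1)C(C)C limonene_core
CC(C)=CCCC(C)=CCO geraniol
CC1CCC2CC(O)CCC2(C)C1 decalinol_core
O=C1OC(=O)c2ccccc12 phthalic_anhydride
O=C1NC(=O)c2ccccc12 phthalimide
CN1C(=O)CC(c2ccccc2)C1=O phenylsuccinimide
c1ccc2nc3ccccc3nc2c1 phenazine
c1ccc2c(c1)ncc1ccccc12 acridine_iso
O=c1cc[nH]c(=O)[nH]1 uracil
Cc1cn(C)c(=O)[nH]c1=O methylthymine
Nc1nc2[nH]cnc2c(=O)[nH]1 guanine
Nc1ncnc2[nH]cnc12 adenine
O=c1[nH]cnc2[nH]cnc12 hypoxanthine
CC12CCC3c4ccc(O)cc4CCC3C1CCC2O estradiol
CC12CCC(=O)C=C1CCC1C2CCC2(C)C1CCC2O testosterone_core
CC(=O)OC1CC2CCC3C(CCC4(C)C3CCC4C(C)=O)C2(C)CC1 steroid_acetate
CN1CCC23c4c5ccc(O)c4OC2C(O)C=CC3C1C5 morphine
COc1ccc2c(c1)C13CCN(C)C(C2)C1C=CC(O)C3 codeine_like
CN1CCC(CC1)=C1c2ccccc2CCc2ccccc12 amitriptyline_core
Clc1ccc2c(c1)C(c1ccccc1)=NCC(=O)N2 benzodiazepine_core
CN1CCN(CC1)C1=Nc2ccccc2Oc2ccccc12 phenoxazine_piperazine
CCN(CC)CCNC(=O)c1ccc(N)cc1 procainamide
CCN(CC)CCOC(=O)c1ccc(N)cc1 procaine
COC(=O)c1ccccc1N benzocaine_iso
CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O warfarin
CC(C)(C)NCC(O)COc1cccc2ccccc12 propranolol
CC(C)NCC(O)COc1ccc(CC(N)=O)cc1 atenolol
CC(C)(C)NCC(O)c1ccc(O)c(CO)c1 salbutamol
CC1=C(CCN2CCC(CC2)c2noc3cc(F)ccc23)C(=O)N2CCCCC2=N1 risperidone
Clc1ccccc1C1=NCC(=O)Nc2ccc(cc12)N(=O)=O nitrazepam_iso
OC(c1ccccc1)(c1ccccc1)C1CCNCC1 pipradrol_core
COc1ccc(cc1)C(=O)CCCN1CCC(O)(CC1)c1ccc(Cl)cc1 haloperidol_methoxy
Fc1ccc(cc1)C(=O)CCCN1CCC(O)(CC1)c1ccc(Cl)cc1 haloperidol
CN(C)CCCN1c2ccccc2Sc2ccccc12 promazine
CN(C)CCCN1c2ccccc2Sc2ccc(Cl)cc12 chlorpromazine
COc1ccc2cc(ccc2c1)C(C)C(=O)O naproxen
OC(=O)Cc1ccccc1Nc1c(Cl)cccc1Cl diclofenac
Cc1ccc(cc1)S(=O)(=O)NC(=O)NN1CCCCCC1 tolazamide_like
CC(=O)Nc1nnc(s1)S(N)(=O)=O acetazolamide
Cc1onc(c1C(=O)Nc1ccccc1)c1ccccc1 oxacillin_fragment
CC1(C)SC2C(NC(=O)Cc3ccccc3)C(=O)N2C1C(=O)O penicillin_g
CN(C)C1C(O)=C(C(N)=O)C(=O)C2(O)C(O)=C3C(=O)c4c(O)cccc4C(C)(O)C3CC12 tetracycline_like
CCCCC(C)(O)C=CC1C(O)CC(=O)C1CCCCCCC(=O)O prostaglandin_like
CC(C)CCCC(C)C1CCC2C3CCC4CC(O)CCC4(C)C3CCC12C cholesterol
CC(CCC(=O)O)C1CCC2C3C(O)CC4CC(O)CCC4(C)C3CC(O)C12C cholic_acid_like
CCC1(CC)C(=O)NC(=O)NC1=O barbital
CCC1(c2ccccc2)C(=O)NC(=O)NC1=O phenobarbital_iso
Cn1c2ccccc2c2ccccc12 n_methylcarbazole
c1ccc2c(c1)[nH]c1ccccc12 carbazole
c1ccc2c(c1)oc1ccccc12 dibenzofuran
c1ccc2c(c1)sc1ccccc12 dibenzothiophene
C1CC2CCC1CC2 bicyclooctane
C1C2CC3CC1CC(C2)C3 adamantane
NC1(CC1)c1ccccc1 phenylcyclopropylamine
C1CC1 cyclopropane
C1CC1N cyclopropylamine
CC1CCCCC1 methylcyclohexane
OC1CCCCC1 cyclohexanol
NC1CCCCC1 cyclohexylamine
N#Cc1ccccc1 benzonitrile
O=Cc1ccccc1 benzaldehyde
CC(=O)c1ccccc1 acetophenone
OCc1ccccc1 benzyl_alcohol
NCc1ccccc1 benzylamine
ClCc1ccccc1 benzyl_chloride
C=Cc1ccccc1 styrene
CCc1ccccc1 ethylbenzene
CCCc1ccccc1 propylbenzene
CC(C)c1ccccc1 cumene
COC(=O)C methylacetate_iso
COC=O methyl_formate
OC=O formic_acid
CC(=O)O acetic_acid
CCC(=O)O propionic_acid
CCCCC(=O)O valeric_acid
CCCCCCCC(=O)O octanoic_acid
CCCCCCCCCCCC(=O)O lauric_acid
CCCCCCCCCCCCCCCC(=O)O palmitic_acid
OCCOCCO diethylene_glycol
COCCOC glyme
CN1CCN(CC1)c1ccccc1 phenylpiperazine_nmethyl
c1ccc(cc1)N1CCNCC1 phenylpiperazine
c1ccc(cc1)N1CCOCC1 phenylmorpholine
c1ccc(cc1)N1CCCCC1 phenylpiperidine
O=C(Nc1ccccc1)Nc1ccccc1 diphenylurea
NC(=O)Nc1ccccc1 phenylurea
NC(=O)N urea
CNC(=O)NC dimethylurea
COC(=O)Nc1ccccc1 methyl_carbanilate
CCOC(=O)N1CCN(CC1)C(=O)OCC piperazine_dicarbamate
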