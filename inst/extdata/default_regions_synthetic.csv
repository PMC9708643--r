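acronym,full_name,higher_order
FRP,Frontal pole,ISO
MOp,Primary motor area,ISO
MOs,Secondary motor area,ISO
SSp,Primary somatosensory area,ISO
SSs,Supplemental somatosensory area,ISO
GU,Gustatory areas,ISO
VISC,Visceral area,ISO
AUDp,Primary auditory area,ISO
AUDd,Dorsal auditory area,ISO
AUDv,Ventral auditory area,ISO
VISp,Primary visual area,ISO
VISl,Lateral visual area,ISO
VISam,Anteromedial visual area,ISO
VISpm,Posteromedial visual area,ISO
ACAd,"Anterior cingulate area, dorsal part",ISO
ACAv,"Anterior cingulate area, ventral part",ISO
PL,Prelimbic area,ISO
ILA,Infralimbic area,ISO
ORBl,"Orbital area, lateral part",ISO
ORBm,"Orbital area, medial part",ISO
ORBvl,"Orbital area, ventrolateral part",ISO
AId,"Agranular insular area, dorsal part",ISO
AIp,"Agranular insular area, posterior part",ISO
AIv,"Agranular insular area, ventral part",ISO
RSPd,"Retrosplenial area, dorsal part",ISO
RSPv,"Retrosplenial area, ventral part",ISO
TEa,Temporal association areas,ISO
PERI,Perirhinal area,ISO
ECT,Ectorhinal area,ISO
CA1,Field CA1,HPF
CA2,Field CA2,HPF
CA3,Field CA3,HPF
DG,Dentate gyrus,HPF
SUB,Subiculum,HPF
PRE,Presubiculum,HPF
POST,Postsubiculum,HPF
PAR,Parasubiculum,HPF
ENTl,"Entorhinal area, lateral part",HPF
ENTm,"Entorhinal area, medial part",HPF
LA,Lateral amygdalar nucleus,AMYG
BLA,Basolateral amygdalar nucleus,AMYG
BMA,Basomedial amygdalar nucleus,AMYG
CEA,Central amygdalar nucleus,AMYG
MEA,Medial amygdalar nucleus,AMYG
COA,Cortical amygdalar area,AMYG
PA,Posterior amygdalar nucleus,AMYG
AAA,Anterior amygdalar area,AMYG
CP,Caudoputamen,STR
ACB,Nucleus accumbens,STR
FS,Fundus of striatum,STR
OT,Olfactory tubercle,STR
LSr,"Lateral septal nucleus, rostral part",STR
LSc,"Lateral septal nucleus, caudal part",STR
SF,Septofimbrial nucleus,STR
SH,Septohippocampal nucleus,STR
GPe,"Globus pallidus, external segment",PAL
GPi,"Globus pallidus, internal segment",PAL
SI,Substantia innominata,PAL
MA,Magnocellular nucleus,PAL
MS,Medial septal nucleus,PAL
BST,Bed nuclei of the stria terminalis,PAL
CENT,Central lobule,CB
CUL,Culmen,CB
DEC,Declive,CB
FOTU,Folium-tuber vermis,CB
PYR,Pyramus,CB
UVU,Uvula,CB
NOD,Nodulus,CB
FL,Flocculus,CB
VAL,Ventral anterior-lateral complex of the thalamus,TH
VM,Ventral medial nucleus of the thalamus,TH
VPL,Ventral posterolateral nucleus of the thalamus,TH
VPM,Ventral posteromedial nucleus of the thalamus,TH
LGd,Dorsal part of the lateral geniculate complex,TH
LGv,Ventral part of the lateral geniculate complex,TH
LP,Lateral posterior nucleus of the thalamus,TH
PO,Posterior complex of the thalamus,TH
AV,Anteroventral nucleus of thalamus,TH
AM,Anteromedial nucleus,TH
AD,Anterodorsal nucleus,TH
LD,Lateral dorsal nucleus of thalamus,TH
MD,Mediodorsal nucleus of thalamus,TH
PVT,Paraventricular nucleus of the thalamus,TH
PT,Parataenial nucleus,TH
RE,Nucleus of reuniens,TH
SO,Supraoptic nucleus,HY
PVH,Paraventricular hypothalamic nucleus,HY
ARH,Arcuate hypothalamic nucleus,HY
DMH,Dorsomedial nucleus of the hypothalamus,HY
VMH,Ventromedial hypothalamic nucleus,HY
LHA,Lateral hypothalamic area,HY
AHN,Anterior hypothalamic nucleus,HY
MM,Medial mammillary nucleus,HY
PH,Posterior hypothalamic nucleus,HY
PMv,Ventral premammillary nucleus,HY
PMd,Dorsal premammillary nucleus,HY
SUM,Supramammillary nucleus,HY
ZI,Zona incerta,HY
SCs,"Superior colliculus, sensory related",MB
SCm,"Superior colliculus, motor related",MB
IC,Inferior colliculus,MB
PAG,Periaqueductal gray,MB
SNr,"Substantia nigra, reticular part",MB
SNc,"Substantia nigra, compact part",MB
VTA,Ventral tegmental area,MB
RN,Red nucleus,MB
MRN,Midbrain reticular nucleus,MB
APN,Anterior pretectal nucleus,MB
PRNc,"Pontine reticular nucleus, caudal part",HB
PB,Parabrachial nucleus,HB
LC,Locus ceruleus,HB
NTS,Nucleus of the solitary tract,HB
DCO,Dorsal cochlear nucleus,HB
IO,Inferior olivary complex,HB
GRN,Gigantocellular reticular nucleus,HB
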