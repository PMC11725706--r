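# Riojasuchus hindlimb muscle origin/insertion topology (bone + region),
# with levels of inference: I unequivocal, II equivocal, prime (') = no
# clear osteological correlate. Attachment coordinates live in model files;
# this table records topology only.
acronym,muscle,origin,insertion,origin_level,insertion_level
IT1,M. iliotibialis 1,Craniodorsal iliac rim (roughening),Cranial tip of cnemial crest of tibia,I,I
IT2,M. iliotibialis 2,Mid-dorsal iliac rim (roughening),Cranial tip of cnemial crest of tibia,I,I
IT3,M. iliotibialis 3,Caudodorsal iliac rim (roughening),Cranial tip of cnemial crest of tibia,I,I
FMTE,M. femorotibialis externus,Lateral femoral shaft between intermuscular lines,Cnemial crest of tibia,I,I
FMTI,M. femorotibialis internus,Medial femoral shaft between intermuscular lines and other muscle scars,Cnemial crest of tibia,I,I
AMB,M. ambiens,Pubic tubercle of proximal pubis,Cnemial crest of tibia; secondary tendon to digital flexor origin,I,I
ILFB,M. iliofibularis,Lateral surface of postacetabular ilium between IF and FTE,Iliofibular tubercle on lateral proximal fibular shaft,I,I
IF,M. iliofemoralis,Lateral surface of ilium above acetabulum,Lesser trochanter of proximal femur,II,II
PIFI1,M. pubo-ischio-femoralis internus 1,Craniomedial side of preacetabular ilium,Craniomedial proximal femoral shaft lateral to fourth trochanter,II,II
PIFI2,M. pubo-ischio-femoralis internus 2,Lumbar (dorsal) vertebrae close to preacetabular ilium; lateral central surfaces,Craniolateral proximal femur near lesser trochanter,II,I'
PIT,M. pubo-ischio-tibialis,One head on craniolateral proximal ischial apron craniad to other ischial muscles,Medial proximal tibia,II,I'
FTI1,M. flexor tibialis internus 1,Lateral surface of distal ischial shaft (tubercle/scar),Medial proximal tibia,II',I'
FTI3,M. flexor tibialis internus 3,Proximal ischial tuberosity (scar),Caudal proximal tibia,II,I'
FTE,M. flexor tibialis externus,Lateral surface of caudoventral corner of postacetabular ilium,Caudal proximal tibia,I',I'
PIFE1,M. puboischiofemoralis externus 1,Cranial surface of pubic apron,Greater trochanter of femur,I,I
PIFE2,M. puboischiofemoralis externus 2,Caudal surface of pubic apron,Greater trochanter of femur,I,I
PIFE3,M. puboischiofemoralis externus 3,Lateral surface of ischial apron caudal to ADD1,Greater trochanter of femur,I,I
ISTR,M. ischiotrochantericus,Medial surface of ischial apron,Lateral side of proximal-most femur near PIFE1-3,I,I
CFB,M. caudofemoralis brevis,Brevis fossa of ilium and proximal caudal vertebrae,Caudolateral side of proximal fourth trochanter,I,I
CFL,M. caudofemoralis longus,Lateral surfaces of haemal arches/chevrons and transverse processes of proximal caudal vertebrae,Fourth trochanter of femur; medial pit,I,I
ADD1,M. adductor femoris 1,Craniolateral surface of ischial apron and shaft,Caudomedial distal femoral shaft,I',I'
ADD2,M. adductor femoris 2,Caudolateral surface of dorsal ischial shaft from scarred groove,Caudolateral distal femoral shaft near caudal intermuscular line,I,I'
GI,M. gastrocnemius internus,Medial side of cnemial crest of proximal tibia,Plantar aponeurosis to metatarsal V; process on distal tarsal 4 and calcaneal tuber; then to digits 2-4 with FDB,I',II'
GE,M. gastrocnemius externus,Proximal to lateral femoral condyle,Plantar aponeurosis to metatarsal V and calcaneum; then to digit 5,I',II'
EDL,M. extensor digitorum longus,Lateral side of the cnemial crest distal to TA origin; and the cranial tibial shaft,Craniomedial surface of proximal metatarsal I,II,II
EDB,M. extensor digitorum brevis,Cranial surfaces of proximal tarsals,Dorsal surfaces of distal phalanges,II',II
TA,M. tibialis anterior,Craniolateral side of the distal femur and lateral cnemial crest,Craniomedial sides of proximal metatarsals II-IV,II,II'
FDL,M. flexor digitorum longus,Proximomedial fibula's shaft,Flexor tubercles of pedal unguals II-V,I',I
FHL,M. flexor hallucis longus,Caudolateral distal femur near GE origin; lateral cnemial crest of the tibia; fossa flexoria; and proximal fibula,Flexor tubercles of pedal unguals I-IV,II',I
FDB,M. flexor digitorum brevis,Plantar aponeurosis,Flexor tubercles of pedal unguals I-V,II',II
FHB,M. flexor hallucis brevis,Distal tarsals and plantar aponeurosis,Caudal side of proximal digit 1 first phalanx; metatarsal I,II,II'
FL,M. fibularis longus,Lateral shaft of fibula distal to ILFB insertion,Lateral side of metatarsal V distal to FB; and calcaneal tuber,I',II
FB,M. fibularis brevis,Distalmost craniolateral shaft of fibula distal to FL origin,Caudolateral side of metatarsal V (and IV) proximal to FL,I',II
PP1,M. interosseous cruris / proximal pronator profundus,Caudolateral proximal tibial shaft,Caudolateral side of metatarsal I and the process of distal tarsal IV,II',II
PP2,M. pronator profundus,Caudomedial fibular shaft,Caudolateral side of metatarsal I and the process of distal tarsal IV,II',II
FC,M. fibulocalcaneus,Caudal fibular surface distal third,Dorsal surface of calcaneal tuber,II',II
AHD,M. abductor hallucis dorsalis,Craniolateral side of distal fibula,Proximodorsal surface of metatarsal I near EDL insertion,II',II
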