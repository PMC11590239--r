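name,kind,group,label
Sex,binary,demographics,Sex (1 = female)
Age,numeric,demographics,Age in years
PHQ,numeric,PHQ,PHQ-9 total score
BISA,numeric,BIS,BIS-11 attentional impulsiveness
BISM,numeric,BIS,BIS-11 motor impulsiveness
BISN,numeric,BIS,BIS-11 non-planning impulsiveness
BIST,numeric,BIS,BIS-11 total score
NAt,count,suicide-outcome,Total number of suicide attempts
AcL,ordinal,suicide-outcome,Lethality of actual attempt (5 levels)
InI,ordinal,suicide-outcome,Intensity of suicidal ideation (1-5)
Alc,binary,CTA-substances,Alcohol before attempt
Mrh,binary,CTA-substances,Cannabis before attempt
Drg,binary,CTA-substances,Other drugs before attempt
Aff,binary,MINI-KID,Affective disorder
Anx,binary,MINI-KID,Anxiety disorder
AlA,binary,MINI-KID,Alcohol-related disorder
DrA,binary,MINI-KID,Drug-related disorder
ADH,binary,MINI-KID,Attention deficit/hyperactivity disorder
CnO,binary,MINI-KID,Conduct/oppositional defiant disorder
Psy,binary,MINI-KID,Psychotic disorder
Etn,binary,MINI-KID,Eating disorder (anorexia/bulimia nervosa)
Adj,binary,MINI-KID,Adjustment disorder
EmA,numeric,CTQ,CTQ-SF emotional abuse
PhA,numeric,CTQ,CTQ-SF physical abuse
SxA,numeric,CTQ,CTQ-SF sexual abuse
EmN,numeric,CTQ,CTQ-SF emotional neglect
PhN,numeric,CTQ,CTQ-SF physical neglect
SDQT,numeric,SDQ,SDQ total difficulties
SDQE,numeric,SDQ,SDQ emotional symptoms
SDQC,numeric,SDQ,SDQ conduct problems
SDQH,numeric,SDQ,SDQ hyperactivity/inattention
SDQPer,numeric,SDQ,SDQ peer problems
SDQPrs,numeric,SDQ,SDQ prosocial behaviour
Mgr,binary,migration,Born abroad
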