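token,tissue,name
cr,bone,cranium
md,bone,mandible
hy,bone,hyoid
st,bone,sternum
ts,bone,thoracic spine
ri,bone,ribs
cl,bone,clavicle
sc,bone,scapula
hu,bone,humerus
C1,bone,cervical vertebra 1
C2,bone,cervical vertebra 2
C3,bone,cervical vertebra 3
C4,bone,cervical vertebra 4
C5,bone,cervical vertebra 5
C6,bone,cervical vertebra 6
C7,bone,cervical vertebra 7
C8,bone,cervical vertebra 8
C9,bone,cervical vertebra 9
ln,ligament,nuchal ligament
ty,cartilage/other,thyroid
asd,muscle,atlantoscapularis dorsalis
asv,muscle,atlantoscapularis ventralis
bc,muscle,biventer cervicis
cal,muscle,longus capitis
cc,muscle,cleidocervicalis
cm,muscle,cleidomastoideus
co,muscle,cleidooccipitalis
col,muscle,longus colli
cx,muscle,complexus
icc,muscle,iliocostalis cervicis
id1,muscle,intertransversarii cervicis dorsales 1
id2,muscle,intertransversarii cervicis dorsales 2
id3,muscle,intertransversarii cervicis dorsales 3
id4,muscle,intertransversarii cervicis dorsales 4
id5,muscle,intertransversarii cervicis dorsales 5
id6,muscle,intertransversarii cervicis dorsales 6
id7,muscle,intertransversarii cervicis dorsales 7
id8,muscle,intertransversarii cervicis dorsales 8
im1,muscle,intertransversarii cervicis mediales 1
im2,muscle,intertransversarii cervicis mediales 2
im3,muscle,intertransversarii cervicis mediales 3
im4,muscle,intertransversarii cervicis mediales 4
is1,muscle,interspinalis 1
is2,muscle,interspinalis 2
is3,muscle,interspinalis 3
is4,muscle,interspinalis 4
is5,muscle,interspinalis 5
is6,muscle,interspinalis 6
is7,muscle,interspinalis 7
is8,muscle,interspinalis 8
iv,muscle,intertransversarii cervicis ventrales (fused)
iv1,muscle,intertransversarii cervicis ventrales 1
iv2,muscle,intertransversarii cervicis ventrales 2
iv3,muscle,intertransversarii cervicis ventrales 3
iv4,muscle,intertransversarii cervicis ventrales 4
iv5,muscle,intertransversarii cervicis ventrales 5
iv6,muscle,intertransversarii cervicis ventrales 6
iv7,muscle,intertransversarii cervicis ventrales 7
iv8,muscle,intertransversarii cervicis ventrales 8
lat,muscle,longus atlantis
lca,muscle,longissimus capitis
lce,muscle,longissimus cervicis
m1,muscle,multifidi 1
m2,muscle,multifidi 2
m3,muscle,multifidi 3
m4,muscle,multifidi 4
m5,muscle,multifidi 5
m6,muscle,multifidi 6
oca,muscle,obliquus capitis caudalis
ocr,muscle,obliquus capitis cranialis
oh,muscle,omohyoideus
rca,muscle,rhomboideus capitis
rce,muscle,rhomboideus cervicis
rci,muscle,rectus capitis dorsalis intermedius
rh,muscle,rhomboideus (undifferentiated)
rl,muscle,rectus capitis lateralis
rma,muscle,rectus capitis dorsalis major
rmi,muscle,rectus capitis dorsalis minor
rv,muscle,rectus capitis ventralis
sce,muscle,spinalis cervicis
scm,muscle,sternocleidomastoideus
sd,muscle,scalenus dorsalis
sh,muscle,sternohyoideus
sm,muscle,scalenus medius
so,muscle,sternooccipitalis
sp,muscle,splenius (undifferentiated)
spca,muscle,splenius capitis
spce,muscle,splenius cervicis
ssca,muscle,semispinalis capitis
ssce,muscle,semispinalis cervicis
sth,muscle,sternothyroideus
stm,muscle,sternomastoideus
stx,muscle,sternomaxillaris
sv,muscle,scalenus ventralis
svc,muscle,serratus ventralis cervicis
tr,muscle,trapezius
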