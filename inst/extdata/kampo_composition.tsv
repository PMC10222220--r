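## Reduced SYNTHETIC stand-in composition matrix: 26 Kampo medicines x
## constituent crude drugs, one pair per row. Compositions are plausible
## simplifications for testing; the full-scale analysis uses a curated
## 148-medicine x 126-crude-drug table in this same two-column format,
## which can be dropped in via the compositionFile argument.
kampo_name	crude_name
kakkonto	Pueraria Root
kakkonto	Ephedra Herb
kakkonto	Jujube
kakkonto	Cinnamon Bark
kakkonto	Peony Root
kakkonto	Glycyrrhiza
kakkonto	Ginger
shakuyakukanzoto	Peony Root
shakuyakukanzoto	Glycyrrhiza
orengedokuto	Coptis Rhizome
orengedokuto	Scutellaria Root
orengedokuto	Phellodendron Bark
orengedokuto	Gardenia Fruit
hangeshashinto	Pinellia Tuber
hangeshashinto	Scutellaria Root
hangeshashinto	Ginger
hangeshashinto	Ginseng
hangeshashinto	Glycyrrhiza
hangeshashinto	Jujube
hangeshashinto	Coptis Rhizome
shosaikoto	Bupleurum Root
shosaikoto	Pinellia Tuber
shosaikoto	Scutellaria Root
shosaikoto	Jujube
shosaikoto	Ginseng
shosaikoto	Glycyrrhiza
shosaikoto	Ginger
saikokaryukotsuboreito	Bupleurum Root
saikokaryukotsuboreito	Pinellia Tuber
saikokaryukotsuboreito	Poria Sclerotium
saikokaryukotsuboreito	Cinnamon Bark
saikokaryukotsuboreito	Scutellaria Root
saikokaryukotsuboreito	Jujube
saikokaryukotsuboreito	Ginseng
saikokaryukotsuboreito	Oyster Shell
saikokaryukotsuboreito	Fossil Bone
saikokaryukotsuboreito	Rhubarb
saikokaryukotsuboreito	Ginger
saireito	Bupleurum Root
saireito	Pinellia Tuber
saireito	Scutellaria Root
saireito	Jujube
saireito	Ginseng
saireito	Glycyrrhiza
saireito	Ginger
saireito	Alisma Rhizome
saireito	Polyporus Sclerotium
saireito	Poria Sclerotium
saireito	Atractylodes Lancea Rhizome
saireito	Cinnamon Bark
daikenchuto	Zanthoxylum Fruit
daikenchuto	Ginger
daikenchuto	Ginseng
bofutsushosan	Scutellaria Root
bofutsushosan	Glycyrrhiza
bofutsushosan	Platycodon Root
bofutsushosan	Gypsum
bofutsushosan	Rhubarb
bofutsushosan	Schizonepeta Spike
bofutsushosan	Gardenia Fruit
bofutsushosan	Peony Root
bofutsushosan	Cnidium Rhizome
bofutsushosan	Japanese Angelica Root
bofutsushosan	Mentha Herb
bofutsushosan	Saposhnikovia Root and Rhizome
bofutsushosan	Ephedra Herb
bofutsushosan	Forsythia Fruit
bofutsushosan	Ginger
bofutsushosan	Atractylodes Rhizome
tokishakuyakusan	Japanese Angelica Root
tokishakuyakusan	Cnidium Rhizome
tokishakuyakusan	Peony Root
tokishakuyakusan	Poria Sclerotium
tokishakuyakusan	Atractylodes Lancea Rhizome
tokishakuyakusan	Alisma Rhizome
keishito	Cinnamon Bark
keishito	Peony Root
keishito	Jujube
keishito	Ginger
keishito	Glycyrrhiza
ninjinto	Ginseng
ninjinto	Glycyrrhiza
ninjinto	Atractylodes Rhizome
ninjinto	Ginger
juzentaihoto	Ginseng
juzentaihoto	Astragalus Root
juzentaihoto	Japanese Angelica Root
juzentaihoto	Peony Root
juzentaihoto	Cnidium Rhizome
juzentaihoto	Rehmannia Root
juzentaihoto	Atractylodes Lancea Rhizome
juzentaihoto	Poria Sclerotium
juzentaihoto	Cinnamon Bark
juzentaihoto	Glycyrrhiza
hochuekkito	Astragalus Root
hochuekkito	Atractylodes Lancea Rhizome
hochuekkito	Ginseng
hochuekkito	Japanese Angelica Root
hochuekkito	Bupleurum Root
hochuekkito	Jujube
hochuekkito	Citrus Unshiu Peel
hochuekkito	Glycyrrhiza
hochuekkito	Cimicifuga Rhizome
hochuekkito	Ginger
inchinkoto	Artemisia Capillaris Flower
inchinkoto	Gardenia Fruit
inchinkoto	Rhubarb
jumihaidokuto	Bupleurum Root
jumihaidokuto	Platycodon Root
jumihaidokuto	Cnidium Rhizome
jumihaidokuto	Poria Sclerotium
jumihaidokuto	Schizonepeta Spike
jumihaidokuto	Saposhnikovia Root and Rhizome
jumihaidokuto	Glycyrrhiza
jumihaidokuto	Quercus Bark
jumihaidokuto	Ginger
tsudosan	Japanese Angelica Root
tsudosan	Rhubarb
tsudosan	Immature Orange
tsudosan	Magnolia Bark
tsudosan	Safflower
tsudosan	Sappan Wood
tsudosan	Glycyrrhiza
kososan	Cyperus Rhizome
kososan	Perilla Herb
kososan	Citrus Unshiu Peel
kososan	Glycyrrhiza
kososan	Ginger
hangekobokuto	Pinellia Tuber
hangekobokuto	Poria Sclerotium
hangekobokuto	Magnolia Bark
hangekobokuto	Perilla Herb
hangekobokuto	Ginger
rikkunshito	Ginseng
rikkunshito	Atractylodes Lancea Rhizome
rikkunshito	Poria Sclerotium
rikkunshito	Pinellia Tuber
rikkunshito	Citrus Unshiu Peel
rikkunshito	Jujube
rikkunshito	Glycyrrhiza
rikkunshito	Ginger
maoto	Ephedra Herb
maoto	Apricot Kernel
maoto	Cinnamon Bark
maoto	Glycyrrhiza
makyokansekito	Ephedra Herb
makyokansekito	Apricot Kernel
makyokansekito	Glycyrrhiza
makyokansekito	Gypsum
choreito	Polyporus Sclerotium
choreito	Poria Sclerotium
choreito	Alisma Rhizome
choreito	Talc
choreito	Donkey-hide Glue
kamishoyosan	Bupleurum Root
kamishoyosan	Peony Root
kamishoyosan	Atractylodes Lancea Rhizome
kamishoyosan	Japanese Angelica Root
kamishoyosan	Poria Sclerotium
kamishoyosan	Gardenia Fruit
kamishoyosan	Moutan Bark
kamishoyosan	Glycyrrhiza
kamishoyosan	Ginger
kamishoyosan	Mentha Herb
nichinto	Pinellia Tuber
nichinto	Poria Sclerotium
nichinto	Citrus Unshiu Peel
nichinto	Glycyrrhiza
nichinto	Ginger
byakkokaninjinto	Gypsum
byakkokaninjinto	Anemarrhena Rhizome
byakkokaninjinto	Glycyrrhiza
byakkokaninjinto	Ginseng
kumibinroto	Areca
kumibinroto	Magnolia Bark
kumibinroto	Cinnamon Bark
kumibinroto	Citrus Unshiu Peel
kumibinroto	Perilla Herb
kumibinroto	Glycyrrhiza
kumibinroto	Rhubarb
kumibinroto	Ginger
seihaito	Scutellaria Root
seihaito	Gardenia Fruit
seihaito	Platycodon Root
seihaito	Poria Sclerotium
seihaito	Citrus Unshiu Peel
seihaito	Japanese Angelica Root
seihaito	Ophiopogon Tuber
seihaito	Glehnia Root and Rhizome
seihaito	Apricot Kernel
goreisan	Alisma Rhizome
goreisan	Polyporus Sclerotium
goreisan	Poria Sclerotium
goreisan	Atractylodes Lancea Rhizome
goreisan	Cinnamon Bark
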