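# SYNTHETIC stand-in alias table mapping raw DRUG-table brand strings to
# canonical Kampo medicine names (two tab-separated columns).
alias	kampo_name
ツムラ葛根湯エキス顆粒	kakkonto
tsumura kakkonto extract granules	kakkonto
クラシエ芍薬甘草湯	shakuyakukanzoto
kracie shakuyakukanzoto extract	shakuyakukanzoto
ツムラ防風通聖散エキス顆粒	bofutsushosan
bofutsushosan extract fine granules	bofutsushosan
ツムラ柴苓湯エキス顆粒	saireito
saireito extract granules	saireito
ツムラ大建中湯エキス顆粒	daikenchuto
daikenchuto extract granules	daikenchuto
ツムラ黄連解毒湯エキス顆粒	orengedokuto
orengedokuto extract granules	orengedokuto
ツムラ半夏瀉心湯エキス顆粒	hangeshashinto
hangeshashinto extract granules	hangeshashinto
ツムラ柴胡加竜骨牡蛎湯エキス顆粒	saikokaryukotsuboreito
saikokaryukotsuboreito extract granules	saikokaryukotsuboreito
ツムラ補中益気湯エキス顆粒	hochuekkito
hochuekkito extract granules	hochuekkito
ツムラ六君子湯エキス顆粒	rikkunshito
rikkunshito extract granules	rikkunshito
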