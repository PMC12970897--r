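name,ingredient
montelukast,montelukast
montelukast sodium,montelukast
singulair,montelukast
kipres,montelukast
montelast,montelukast
montair,montelukast
zafirlukast,zafirlukast
accolate,zafirlukast
pranlukast,pranlukast
pranlukast hydrate,pranlukast
onon,pranlukast
azlaire,pranlukast
ibudilast,ibudilast
ketas,ibudilast
pinatos,ibudilast
eyevinal,ibudilast
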