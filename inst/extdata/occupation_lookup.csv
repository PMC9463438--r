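occ_detail,class5,prestige11
none_or_unemployed,none_other,1
homemaker,none_other,1
laborer,manual_blue_collar,2
farm_worker,manual_blue_collar,2
service_worker,sales_service_admin,3
machine_operator,manual_blue_collar,3
craftsperson,manual_blue_collar,4
military,none_other,4
clerical,sales_service_admin,5
sales_worker,sales_service_admin,6
transport_operator,manual_blue_collar,5
technician,professional_managerial,7
teacher_nurse,professional_managerial,8
manager,professional_managerial,9
engineer_scientist,professional_managerial,10
professional,professional_managerial,11
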